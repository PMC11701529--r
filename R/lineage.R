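## Lineage-relationship inference: cell types sharing clones show correlated
## barcode signatures. Spearman correlation over clones for every cell-type
## pair, plus an average-linkage dendrogram on 1 - rho as a lineage tree.

#' Spearman rank correlation
#'
#' Pearson correlation of tie-aware average ranks. A constant vector has no
#' rank ordering; its correlation is defined as 0 (uninformative) with a
#' warning, so downstream matrices stay NaN-free.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) .stopf("length mismatch: %d vs %d",
                                     length(x), length(y))
  if (length(x) < 3L) .stopf("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) .stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .warnf("constant vector: Spearman correlation defined as 0")
    return(0)
  }
  stats::cor(x, y, method = "spearman")
}

#' Lineage relationships between cell types
#'
#' Computes the Spearman correlation of barcode signatures (per-clone cell
#' counts, or fate-map fractions) between every pair of cell types. High
#' correlation implies a shared clonal origin of the two types.
#'
#' Clones with zero cells in every selected label are removed first. By
#' default the clone universe is chosen pairwise: clones absent from both
#' members of a pair carry no ordering information and are excluded for that
#' pair; `universe = "global"` keeps the full filtered clone set for every
#' pair.
#'
#' @param clone_matrix a [clone_matrix()].
#' @param subset optional character vector of cell-type labels to analyse.
#' @param signature `"counts"` (default, raw per-clone counts) or
#'   `"fate_map"` (row-normalized fractions).
#' @param universe `"pairwise"` (default) or `"global"` clone universe.
#' @return object of class `lineage_correlation`: list with `labels`, `rho`
#'   (symmetric, unit diagonal), `n_clones_used`.
#' @export
lineage_relationship <- function(clone_matrix, subset = NULL,
                                 signature = c("counts", "fate_map"),
                                 universe = c("pairwise", "global")) {
  stopifnot(inherits(clone_matrix, "clone_matrix"))
  signature <- match.arg(signature)
  universe <- match.arg(universe)
  labs <- colnames(clone_matrix)
  if (!is.null(subset)) {
    bad <- setdiff(subset, labs)
    if (length(bad) > 0L) .stopf("unknown cell type: %s", bad[1L])
    labs <- labs[labs %in% subset]
  }
  if (length(labs) < 2L) .stopf("need at least 2 cell types")
  m <- if (signature == "fate_map") unclass(fate_mapping(clone_matrix)) else
    unclass(clone_matrix)
  m <- m[, labs, drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 3L)
    .stopf("fewer than 3 clones observed in the selected cell types")
  k <- length(labs)
  rho <- diag(1, k)
  dimnames(rho) <- list(labs, labs)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      use <- if (universe == "pairwise") m[, i] > 0 | m[, j] > 0 else
        rep(TRUE, nrow(m))
      r <- if (sum(use) < 3L) {
        .warnf("pair %s/%s: fewer than 3 usable clones, rho set to 0",
               labs[i], labs[j])
        0
      } else {
        suppressWarnings(spearman_rho(m[use, i], m[use, j]))
      }
      rho[i, j] <- rho[j, i] <- r
    }
  }
  structure(list(labels = labs, rho = rho, n_clones_used = nrow(m)),
            class = "lineage_correlation")
}

#' @export
print.lineage_correlation <- function(x, ...) {
  cat(sprintf("lineage_correlation: %d cell types, %d clones\n",
              length(x$labels), x$n_clones_used))
  print(round(x$rho, 3))
  invisible(x)
}

#' Lineage dendrogram from a correlation matrix
#'
#' Hierarchical clustering of cell types on the distance `1 - rho`
#' (average linkage by default), returned as a Newick string whose branch
#' lengths reflect merge heights. Two labels yield `(A:h,B:h);` with
#' `h = (1 - rho)/2`.
#'
#' @param corr a `lineage_correlation` from [lineage_relationship()].
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return Newick string (terminated by `;`).
#' @export
lineage_tree <- function(corr, linkage = c("average", "complete", "single")) {
  stopifnot(inherits(corr, "lineage_correlation"))
  linkage <- match.arg(linkage)
  if (any(!is.finite(corr$rho))) .stopf("non-finite correlation values")
  if (length(corr$labels) < 2L) .stopf("need at least 2 labels")
  d <- stats::as.dist(1 - corr$rho)
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}
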