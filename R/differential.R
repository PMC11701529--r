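## Fate-bias-conditioned differential testing: negative-binomial GLM
## likelihood-ratio tests for RNA counts, rank-sum tests for ATAC
## accessibility, with the selection rule p < 0.05 and |log2FC| > 0.5.

.log2fc_means <- function(mean_a, mean_b, eps = 1) {
  if (mean_a <= -eps || mean_b <= -eps) return(NA_real_)
  log2((mean_a + eps) / (mean_b + eps))
}

#' Negative-binomial differential test for one feature
#'
#' Fits a negative-binomial regression of counts on the group indicator with
#' a library-size offset (log link, gene-wise ML dispersion via
#' [MASS::glm.nb()], which iterates from a method-of-moments start) and
#' compares it to the intercept-only model by likelihood-ratio test. When
#' the dispersion estimate diverges (Poisson-like data) the test falls back
#' to a Poisson GLM LRT, its small-dispersion limit. The fold change is
#' `log2((mean_a + 1)/(mean_b + 1))` on offset-normalized means.
#'
#' @param counts_a,counts_b non-negative integer count vectors, >= 3 cells
#'   per group.
#' @param sf_a,sf_b positive size factors per cell (library-size offsets);
#'   default 1.
#' @return list with `log2fc`, `p_value`, `mean_a`, `mean_b`. A feature that
#'   is all-zero in both groups returns `p_value = 1`, `log2fc = 0`.
#' @export
nb_test <- function(counts_a, counts_b, sf_a = NULL, sf_b = NULL) {
  .check_counts <- function(v, nm) {
    if (length(v) < 3L) .stopf("group %s has fewer than 3 cells", nm)
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      .stopf("group %s: counts must be non-negative integers", nm)
  }
  .check_counts(counts_a, "a"); .check_counts(counts_b, "b")
  sf_a <- sf_a %||% rep(1, length(counts_a))
  sf_b <- sf_b %||% rep(1, length(counts_b))
  if (any(sf_a <= 0) || any(sf_b <= 0)) .stopf("size factors must be > 0")
  mean_a <- mean(counts_a / sf_a)
  mean_b <- mean(counts_b / sf_b)
  if (all(counts_a == 0) && all(counts_b == 0))
    return(list(log2fc = 0, p_value = 1, mean_a = 0, mean_b = 0))
  y <- c(counts_a, counts_b)
  g <- factor(rep(c("a", "b"), c(length(counts_a), length(counts_b))),
              levels = c("b", "a"))
  off <- log(c(sf_a, sf_b))
  p <- tryCatch({
    full <- suppressWarnings(MASS::glm.nb(y ~ g + offset(off)))
    null <- suppressWarnings(
      MASS::glm.nb(y ~ 1 + offset(off), init.theta = full$theta))
    lr <- 2 * (stats::logLik(full) - stats::logLik(null))
    stats::pchisq(max(0, as.numeric(lr)), df = 1, lower.tail = FALSE)
  }, error = function(e) {
    full <- stats::glm(y ~ g + offset(off), family = stats::poisson())
    null <- stats::glm(y ~ 1 + offset(off), family = stats::poisson())
    stats::pchisq(max(0, null$deviance - full$deviance), df = 1,
                  lower.tail = FALSE)
  })
  list(log2fc = .log2fc_means(mean_a, mean_b), p_value = p,
       mean_a = mean_a, mean_b = mean_b)
}

#' Wilcoxon rank-sum differential test for one feature
#'
#' Two-sided rank-sum test. For `n_a + n_b <= 12` the p-value is exact by
#' enumeration of all group assignments of the pooled (tie-averaged) ranks:
#' the probability that the rank sum deviates from its null mean at least as
#' much as observed. Larger samples use the normal approximation with tie
#' and continuity corrections.
#'
#' @param values_a,values_b numeric vectors, >= 2 values per group.
#' @param eps pseudocount for the fold change on group means; default 1.
#' @return list with `log2fc`, `p_value`, `mean_a`, `mean_b`, and `exact`
#'   (which branch was used).
#' @export
wilcoxon_test <- function(values_a, values_b, eps = 1) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    .stopf("each group needs at least 2 values")
  if (any(!is.finite(values_a)) || any(!is.finite(values_b)))
    .stopf("non-finite values")
  na <- length(values_a); nb <- length(values_b); n <- na + nb
  exact <- n <= 12L
  if (exact) {
    r <- rank(c(values_a, values_b))
    w_obs <- sum(r[seq_len(na)])
    mu <- na * (n + 1) / 2
    sets <- utils::combn(n, na)
    ws <- colSums(matrix(r[sets], nrow = na))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE,
                         correct = TRUE)$p.value)
  }
  list(log2fc = .log2fc_means(mean(values_a), mean(values_b), eps),
       p_value = p, mean_a = mean(values_a), mean_b = mean(values_b),
       exact = exact)
}

#' Fate-bias-conditioned differential expression / accessibility
#'
#' Partitions the cells of one cell type by the fate-bias label of their
#' clone and tests every feature between the two bias groups: per-gene
#' negative-binomial LRT for RNA, per-peak Wilcoxon on normalized
#' accessibility for ATAC. Features with `p < p_cut` and
#' `|log2FC| > lfc_cut` are flagged significant (defaults 0.05 and 0.5).
#'
#' @param counts a `count_matrix` from [read_count_matrix()] (or the same
#'   structure built in memory).
#' @param cells data frame of cell records with `cell_id`, `cell_type` and
#'   `clone_id` (from barcode resolution).
#' @param calls fate-bias calls: a `fate_bias` object or its `calls` data
#'   frame.
#' @param cell_type the cell type whose cells are compared.
#' @param bias_a,bias_b the two fate-bias groups: a target cell-type label
#'   (selecting clones called biased toward it) or `"balanced"`.
#' @param p_cut,lfc_cut significance thresholds.
#' @param min_cells minimum cells per group; default 3.
#' @return data frame of class `diff_result` with columns `feature_id`,
#'   `mean_a`, `mean_b`, `log2_fold_change`, `p_value`, `fdr` (BH, reported
#'   for convenience; selection uses the raw p), `significant`; sorted by
#'   p then |log2FC| descending, ties lexicographic.
#' @export
fate_bias_diff <- function(counts, cells, calls, cell_type, bias_a, bias_b,
                           p_cut = 0.05, lfc_cut = 0.5, min_cells = 3L) {
  stopifnot(inherits(counts, "count_matrix"), is.data.frame(cells))
  if (inherits(calls, "fate_bias")) calls <- calls$calls
  for (col in c("cell_id", "cell_type", "clone_id"))
    if (is.null(cells[[col]])) .stopf("cells is missing column '%s'", col)
  clone_group <- function(bias) {
    if (identical(bias, "balanced"))
      calls$clone_id[calls$label == "balanced"]
    else calls$clone_id[calls$label == paste(bias, "biased")]
  }
  pick <- function(bias) {
    sel <- cells$cell_type == cell_type & !is.na(cells$clone_id) &
      cells$clone_id %in% clone_group(bias)
    cells$cell_id[sel]
  }
  ids_a <- intersect(pick(bias_a), counts$cell_ids)
  ids_b <- intersect(pick(bias_b), counts$cell_ids)
  if (length(ids_a) < min_cells)
    .stopf("bias group '%s' has %d %s cells (< %d)", bias_a, length(ids_a),
           cell_type, min_cells)
  if (length(ids_b) < min_cells)
    .stopf("bias group '%s' has %d %s cells (< %d)", bias_b, length(ids_b),
           cell_type, min_cells)
  m <- base::as.matrix(counts$values[, c(ids_a, ids_b), drop = FALSE])
  grp <- rep(c("a", "b"), c(length(ids_a), length(ids_b)))
  tot <- colSums(m)
  sf <- tot / stats::median(tot[tot > 0])
  sf[sf <= 0] <- min(sf[sf > 0], 1)
  res <- lapply(seq_len(nrow(m)), function(i) {
    ya <- m[i, grp == "a"]; yb <- m[i, grp == "b"]
    if (counts$modality == "rna") {
      r <- nb_test(ya, yb, sf_a = sf[grp == "a"], sf_b = sf[grp == "b"])
    } else {
      r <- wilcoxon_test(ya / sf[grp == "a"], yb / sf[grp == "b"])
    }
    data.frame(feature_id = counts$feature_ids[i], mean_a = r$mean_a,
               mean_b = r$mean_b, log2_fold_change = r$log2fc,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- out$p_value < p_cut &
    !is.na(out$log2_fold_change) & abs(out$log2_fold_change) > lfc_cut
  out <- out[order(out$p_value, -abs(out$log2_fold_change), out$feature_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diff_result", class(out))
  out
}

#' Volcano-plot table
#'
#' Reshapes differential results for volcano plotting; `-log10(p)` is capped
#' at 300.
#'
#' @param results a `diff_result` from [fate_bias_diff()].
#' @return data frame (`feature`, `log2fc`, `neg_log10_p`, `significant`).
#' @export
volcano_table <- function(results) {
  stopifnot(is.data.frame(results))
  data.frame(feature = results$feature_id,
             log2fc = results$log2_fold_change,
             neg_log10_p = pmin(-log10(pmax(results$p_value, 1e-300)), 300),
             significant = results$significant,
             stringsAsFactors = FALSE)
}
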