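## Clone fate-outcome normalization and fate-bias calling. A clone's fate
## map row is its cell-count distribution over cell types; fate bias is a
## statistically significant over-occupancy of one target (set of) cell
## type(s) relative to random sampling of all barcoded cells, tested with a
## one-sided Fisher's exact test under Benjamini-Hochberg FDR control.

#' Fate-outcome normalization
#'
#' Converts a clone matrix to per-clone fate fractions:
#' `value[b, A] = counts[b, A] / sum_A counts[b, A]`, the normalized value of
#' barcode `b` in cell type `A`. Every row sums to 1.
#'
#' @param clone_matrix a [clone_matrix()].
#' @return numeric matrix of class `fate_map`, same dimnames, rows summing
#'   to 1.
#' @export
fate_mapping <- function(clone_matrix) {
  stopifnot(inherits(clone_matrix, "clone_matrix"))
  size <- rowSums(clone_matrix)
  if (any(size == 0)) .stopf("clone matrix has an all-zero row")
  fm <- unclass(clone_matrix) / size
  class(fm) <- c("fate_map", "matrix", "array")
  fm
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Enrichment-sided: with `a` clone cells in the target set, `b` clone cells
#' elsewhere, `c` other cells in the target and `d` other cells elsewhere,
#' the p-value is the hypergeometric upper tail `P(X >= a)` for
#' `X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b)`. The odds ratio is the
#' sample estimate `ad/bc` (`Inf` when `bc = 0` and `ad > 0`).
#'
#' @param a,b,c,d non-negative integer cell counts; `a + b >= 1`.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`
#'   (sum of all table probabilities not exceeding the observed one).
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_one_sided <- function(a, b, c, d, alternative = "greater") {
  v <- c(a, b, c, d)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    .stopf("table entries must be non-negative integers")
  if (sum(v) == 0) .stopf("all-zero 2x2 table")
  if (a + b < 1) .stopf("need a + b >= 1 (non-empty clone)")
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else if (a * d == 0 && (a + d) > 0 && (b + c) > 0) 0 else NaN
  } else (a * d) / (b * c)
  p <- switch(alternative,
    greater = stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE),
    two.sided = {
      support <- max(0, (a + b) - (b + d)):min(a + b, a + c)
      dens <- stats::dhyper(support, a + c, b + d, a + b)
      sum(dens[dens <= stats::dhyper(a, a + c, b + d, a + b) * (1 + 1e-7)])
    },
    .stopf("unknown alternative '%s'", alternative))
  list(odds_ratio = or, p_value = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; output order matches input
#' order.
#'
#' @param p_values numeric vector in `[0, 1]`, non-empty.
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) .stopf("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Clone fate-bias calling
#'
#' For every clone x target set, builds the 2x2 occupancy table (clone cells
#' in / out of the target vs all other cells in / out), applies the
#' enrichment-sided Fisher test, adjusts all tests jointly by
#' Benjamini-Hochberg, and labels each clone by the target of its
#' minimum-FDR significant enrichment (`"<target> biased"`), or
#' `"balanced"` when no test reaches `fdr < alpha` with odds ratio > 1.
#' Clones smaller than `min_clone_size` are reported as `"untested"` — a
#' single cell cannot evidence bias.
#'
#' @param clone_matrix a [clone_matrix()].
#' @param targets named list of label sets (e.g.
#'   `list(Lymphoid = c("T", "B", "NK"))`); default: one singleton set per
#'   cell-type column.
#' @param alpha FDR threshold; default 0.05.
#' @param alternative sidedness of the Fisher test, `"greater"` by default.
#' @param stratify_by_target adjust p-values within each target separately
#'   instead of pooling all clone x target tests; default `FALSE`.
#' @param min_clone_size smallest clone that is tested; default 2.
#' @return object of class `fate_bias`: list with
#'   * `calls` — one row per clone (`clone_id`, `label`, `target_label`,
#'     `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `fdr`), the reported test
#'     being the minimum-FDR one (ties: larger `a`, then lexicographic
#'     target);
#'   * `tests` — the full clone x target test table;
#'   * `significant` — all significant enriched tests (for multi-label use);
#'   * `alpha`, `targets`.
#' @export
clone_fate_bias <- function(clone_matrix, targets = NULL, alpha = 0.05,
                            alternative = "greater",
                            stratify_by_target = FALSE,
                            min_clone_size = 2) {
  stopifnot(inherits(clone_matrix, "clone_matrix"))
  labs <- colnames(clone_matrix)
  if (is.null(targets)) {
    targets <- as.list(labs)
    names(targets) <- labs
  }
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    .stopf("targets must be a named list")
  for (nm in names(targets)) {
    bad <- setdiff(targets[[nm]], labs)
    if (length(bad) > 0L)
      .stopf("target '%s' uses label absent from the clone matrix: %s",
             nm, bad[1L])
  }
  cm <- unclass(clone_matrix)
  size <- rowSums(cm)
  total <- sum(cm)
  in_target <- vapply(targets, function(set)
    rowSums(cm[, set, drop = FALSE]), numeric(nrow(cm)))
  if (nrow(cm) == 1L) in_target <- matrix(in_target, nrow = 1L)
  target_total <- colSums(in_target)

  grid <- expand.grid(clone = seq_len(nrow(cm)),
                      target = seq_along(targets))
  a <- in_target[cbind(grid$clone, grid$target)]
  b <- size[grid$clone] - a
  cc <- target_total[grid$target] - a
  d <- total - a - b - cc
  or <- ifelse(b * cc == 0, ifelse(a * d > 0, Inf, ifelse(b + cc > 0, 0, NaN)),
               (a * d) / (b * cc))
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  } else {
    vapply(seq_along(a), function(i)
      fisher_exact_one_sided(a[i], b[i], cc[i], d[i],
                             alternative = alternative)$p_value,
      numeric(1))
  }
  tested <- size[grid$clone] >= min_clone_size
  p[!tested] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  if (any(tested)) {
    if (stratify_by_target) {
      for (tg in seq_along(targets)) {
        sel <- tested & grid$target == tg
        if (any(sel)) fdr[sel] <- bh_adjust(p[sel])
      }
    } else {
      fdr[tested] <- bh_adjust(p[tested])
    }
  }
  tests <- data.frame(clone_id = rownames(cm)[grid$clone],
                      target_label = names(targets)[grid$target],
                      a = as.integer(a), b = as.integer(b),
                      c = as.integer(cc), d = as.integer(d),
                      odds_ratio = or, p_value = pmin(1, p), fdr = fdr,
                      stringsAsFactors = FALSE)

  sig <- tests[!is.na(tests$fdr) & tests$fdr < alpha & tests$odds_ratio > 1, ,
               drop = FALSE]
  calls <- lapply(seq_len(nrow(cm)), function(i) {
    id <- rownames(cm)[i]
    if (!size[i] >= min_clone_size) {
      row <- tests[tests$clone_id == id, , drop = FALSE][1L, ]
      row$label <- "untested"
      return(row)
    }
    mine_sig <- sig[sig$clone_id == id, , drop = FALSE]
    pool <- if (nrow(mine_sig) > 0L) mine_sig else
      tests[tests$clone_id == id, , drop = FALSE]
    pool <- pool[order(pool$fdr, -pool$a, pool$target_label), , drop = FALSE]
    row <- pool[1L, ]
    row$label <- if (nrow(mine_sig) > 0L)
      paste(row$target_label, "biased") else "balanced"
    row
  })
  calls <- do.call(rbind, calls)
  calls <- calls[, c("clone_id", "label", "target_label", "a", "b", "c", "d",
                     "odds_ratio", "p_value", "fdr")]
  rownames(calls) <- NULL
  rownames(sig) <- NULL
  structure(list(calls = calls, tests = tests, significant = sig,
                 alpha = alpha, targets = targets),
            class = "fate_bias")
}

#' @export
print.fate_bias <- function(x, ...) {
  n_biased <- sum(x$calls$label != "balanced" & x$calls$label != "untested")
  cat(sprintf("fate_bias: %d clones, %d targets, %d biased at FDR < %g\n",
              nrow(x$calls), length(x$targets), n_biased, x$alpha))
  invisible(x)
}

#' Summarize fate-bias calls
#'
#' Fraction of clones (or cells) per fate-bias label, e.g. the share of
#' progenitor clones biased toward each mature lineage.
#'
#' @param calls a `fate_bias` object from [clone_fate_bias()] or its `calls`
#'   data frame.
#' @param restrict_to optional vector of clone ids to summarize.
#' @param weight `"clone"` (default; each clone counts once) or `"cell"`
#'   (clones weighted by size).
#' @return data frame (`label`, `n_clones`, `fraction`), fractions summing
#'   to 1, sorted by descending fraction then label.
#' @export
summarize_fate_bias <- function(calls, restrict_to = NULL,
                                weight = c("clone", "cell")) {
  weight <- match.arg(weight)
  if (inherits(calls, "fate_bias")) calls <- calls$calls
  stopifnot(is.data.frame(calls))
  if (!is.null(restrict_to))
    calls <- calls[calls$clone_id %in% restrict_to, , drop = FALSE]
  if (nrow(calls) == 0L) .stopf("no fate-bias calls to summarize")
  w <- if (weight == "cell") calls$a + calls$b else rep(1, nrow(calls))
  agg <- stats::aggregate(list(wt = w, one = rep(1L, nrow(calls))),
                          by = list(label = calls$label), FUN = sum)
  out <- data.frame(label = agg$label,
                    n_clones = as.integer(agg$one),
                    fraction = agg$wt / sum(agg$wt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
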