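## PWM motif scanning with an exact null score distribution. Scores are
## log2 odds of the motif model against a 0-order background, discretized
## to a fixed grain; the null distribution over all words is computed by
## dynamic programming across positions, and the match threshold is the
## smallest score whose background tail probability drops below `p_cutoff`.

.pwm_probs <- function(p, pseudocount) {
  m <- p$matrix + pseudocount
  m <- sweep(m, 2L, colSums(m), "/")
  if (any(m <= 0)) .stopf("degenerate PWM column in motif %s", p$motif_id)
  m
}

.score_int <- function(probs, background, grain) {
  s <- log2(probs / background)  # background recycles down the 4 rows
  matrix(as.integer(round(s / grain)), nrow = 4L,
         dimnames = dimnames(probs))
}

.score_dist_int <- function(si, background) {
  clo <- 0L; p <- 1
  for (j in seq_len(ncol(si))) {
    col <- si[, j]
    newlo <- clo + min(col)
    newp <- numeric(length(p) + max(col) - min(col))
    for (k in 1:4) {
      at <- (clo + col[k]) - newlo
      idx <- seq_along(p) + at
      newp[idx] <- newp[idx] + background[k] * p
    }
    p <- newp; clo <- newlo
  }
  list(scores = clo + seq_along(p) - 1L, probs = p)
}

#' Exact PWM score distribution under the background model
#'
#' The distribution of the discretized log-odds score of a random word drawn
#' i.i.d. from the background, computed exactly by dynamic programming over
#' motif positions (equivalent to enumerating all `4^L` words).
#'
#' @param pwm a [pwm()].
#' @param background length-4 background probabilities; defaults to the
#'   motif's own background.
#' @param pseudocount added to PWM probabilities before log-odds; default
#'   0.008.
#' @param grain score discretization step in log-odds units; default 1e-3.
#' @return data frame (`score`, `prob`) over the achievable score support;
#'   probabilities sum to 1.
#' @export
pwm_score_distribution <- function(pwm, background = NULL,
                                   pseudocount = 0.008, grain = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  background <- background %||% pwm$background
  background <- background / sum(background)
  probs <- .pwm_probs(pwm, pseudocount)
  si <- .score_int(probs, background, grain)
  d <- .score_dist_int(si, background)
  keep <- d$probs > 0
  data.frame(score = d$scores[keep] * grain, prob = d$probs[keep])
}

#' PWM match-score threshold at a p-value cutoff
#'
#' The smallest discretized log-odds score `s` with background tail
#' probability `P(score >= s) <= p_cutoff`. When even a perfect match is
#' more probable than `p_cutoff` under the background (short or weak
#' motifs), the threshold exceeds the maximum achievable score and no
#' window can match.
#'
#' @inheritParams pwm_score_distribution
#' @param p_cutoff match p-value cutoff in `(0, 1)`; default `5e-5`.
#' @return threshold in log-odds units, with attributes `int` (grid units),
#'   `grain`, `max_score` (grid units) and `attainable` (whether any word
#'   reaches it).
#' @export
pwm_score_threshold <- function(pwm, p_cutoff = 5e-5, background = NULL,
                                pseudocount = 0.008, grain = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff >= 1)
    .stopf("p_cutoff must lie in (0, 1)")
  background <- background %||% pwm$background
  background <- background / sum(background)
  probs <- .pwm_probs(pwm, pseudocount)
  si <- .score_int(probs, background, grain)
  d <- .score_dist_int(si, background)
  tail <- rev(cumsum(rev(d$probs)))
  ok <- which(tail <= p_cutoff)
  thr_int <- if (length(ok) > 0L) d$scores[ok[1L]] else
    max(d$scores) + 1L
  structure(thr_int * grain, int = thr_int, grain = grain,
            max_score = max(d$scores),
            attainable = length(ok) > 0L)
}

.encode_dna <- function(seq, what) {
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) .stopf("%s: non-ACGTN character", what)
  code <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
  code  # N -> NA; windows containing NA never match
}

#' Scan regions for motif matches
#'
#' A region matches a motif when any window on either strand scores at or
#' above the motif's threshold at `p_cutoff` (best-window, any-hit
#' semantics). The reverse strand is scanned with the reverse-complemented
#' PWM; windows containing `N` never match.
#'
#' @param pwms list of [pwm()] objects (or a single one).
#' @param sequences region sequences: named character vector or a
#'   `Biostrings::DNAStringSet` (e.g. from `readDNAStringSet()`).
#' @param p_cutoff match p-value cutoff; default `5e-5`.
#' @param background `"estimate"` (default; 0-order base composition of the
#'   supplied sequences), `"uniform"`, or a length-4 numeric vector.
#' @inheritParams pwm_score_distribution
#' @return logical region x motif matrix of class `motif_match_matrix`.
#' @export
scan_regions <- function(pwms, sequences, p_cutoff = 5e-5,
                         background = "estimate", pseudocount = 0.008,
                         grain = 1e-3) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(all(vapply(pwms, inherits, logical(1), "pwm")))
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- sprintf("region_%d", seq_along(sequences))
  codes <- lapply(seq_along(sequences), function(i)
    .encode_dna(sequences[[i]], names(sequences)[i]))
  bg <- if (is.numeric(background)) {
    background / sum(background)
  } else if (identical(background, "uniform")) {
    rep(0.25, 4)
  } else if (identical(background, "estimate")) {
    counts <- tabulate(unlist(codes), nbins = 4L)
    if (sum(counts) == 0L) rep(0.25, 4) else {
      f <- (counts + 1) / sum(counts + 1)  # add-one: keep log-odds finite
      f
    }
  } else .stopf("background must be 'estimate', 'uniform' or 4 numbers")
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  out <- matrix(FALSE, length(sequences), length(pwms),
                dimnames = list(names(sequences), ids))
  for (mi in seq_along(pwms)) {
    probs <- .pwm_probs(pwms[[mi]], pseudocount)
    si_f <- .score_int(probs, bg, grain)
    si_r <- .score_int(probs[4:1, rev(seq_len(ncol(probs))), drop = FALSE],
                       bg, grain)
    thr <- attr(pwm_score_threshold(pwms[[mi]], p_cutoff, background = bg,
                                    pseudocount = pseudocount, grain = grain),
                "int")
    L <- ncol(si_f)
    for (ri in seq_along(codes)) {
      cv <- codes[[ri]]
      nwin <- length(cv) - L + 1L
      if (nwin < 1L) next
      sf <- numeric(nwin); sr <- numeric(nwin)
      for (j in seq_len(L)) {
        cj <- cv[j:(j + nwin - 1L)]
        sf <- sf + si_f[cbind(cj, j)]
        sr <- sr + si_r[cbind(cj, j)]
      }
      hits <- c(sf, sr)
      out[ri, mi] <- any(!is.na(hits) & hits >= thr)
    }
  }
  class(out) <- c("motif_match_matrix", class(out))
  out
}

#' Motif enrichment between region sets
#'
#' One-sided hypergeometric test (via [fisher_exact_one_sided()]) of motif
#' match counts in a foreground region set against a disjoint background
#' set, Benjamini-Hochberg adjusted across motifs. The enrichment score is
#' the log2 ratio of smoothed match rates `(matches + 0.5)/(regions + 1)`.
#'
#' @param matches a `motif_match_matrix` from [scan_regions()].
#' @param foreground,background disjoint, non-empty character vectors of
#'   region ids.
#' @return data frame (`motif_id`, `n_fg_match`, `n_fg`, `n_bg_match`,
#'   `n_bg`, `odds_ratio`, `p_value`, `fdr`, `log2_enrichment`), sorted by
#'   fdr then p then motif id.
#' @export
motif_enrichment <- function(matches, foreground, background) {
  stopifnot(inherits(matches, "motif_match_matrix"))
  if (length(foreground) == 0L || length(background) == 0L)
    .stopf("foreground and background must be non-empty")
  if (length(intersect(foreground, background)) > 0L)
    .stopf("foreground and background overlap")
  missing <- setdiff(c(foreground, background), rownames(matches))
  if (length(missing) > 0L)
    .stopf("region id not in the match matrix: %s", missing[1L])
  n_fg <- length(foreground); n_bg <- length(background)
  rows <- lapply(colnames(matches), function(m) {
    a <- sum(matches[foreground, m])
    cc <- sum(matches[background, m])
    ft <- fisher_exact_one_sided(a, n_fg - a, cc, n_bg - cc)
    data.frame(motif_id = m, n_fg_match = a, n_fg = n_fg,
               n_bg_match = cc, n_bg = n_bg, odds_ratio = ft$odds_ratio,
               p_value = ft$p_value,
               log2_enrichment = log2(((a + 0.5) / (n_fg + 1)) /
                                        ((cc + 0.5) / (n_bg + 1))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[, c("motif_id", "n_fg_match", "n_fg", "n_bg_match", "n_bg",
                 "odds_ratio", "p_value", "fdr", "log2_enrichment")]
  out <- out[order(out$fdr, out$p_value, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
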