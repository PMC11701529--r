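# Independent oracles, coded from first principles so they never share a
# code path with the implementation they check.

# One-sided Fisher p by explicit hypergeometric enumeration with choose().
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  ks <- a:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Textbook BH step-up: adj_(i) = min_{j >= i} min(1, m p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# Spearman as manual rank-then-Pearson with average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exact two-sided rank-sum p by enumerating every group assignment and
# re-ranking from scratch (deviation of the rank sum from its null mean).
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  mu <- na * (n + 1) / 2
  obs <- abs(sum(r[seq_len(na)]) - mu)
  sets <- utils::combn(n, na)
  devs <- apply(sets, 2L, function(idx) abs(sum(r[idx]) - mu))
  mean(devs >= obs - 1e-9)
}

# PWM score distribution by brute-force enumeration of all 4^L words,
# reproducing the implementation's discretization contract.
oracle_pwm_dist <- function(p, background = p$background,
                            pseudocount = 0.008, grain = 1e-3) {
  m <- p$matrix + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  si <- matrix(as.integer(round(log2(m / background) / grain)), nrow = 4)
  L <- ncol(si)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- integer(nrow(words)); pr <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    w <- words[i, ]
    sc[i] <- sum(si[cbind(w, seq_len(L))])
    pr[i] <- prod(background[w])
  }
  agg <- tapply(pr, sc, sum)
  data.frame(score = as.integer(names(agg)) * grain,
             prob = as.numeric(agg))
}

rc_dna <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# small deterministic clone matrix used across files
toy_clone_matrix <- function() {
  clone_matrix(matrix(c(2L, 0L, 1L, 1L, 0L, 3L), nrow = 3, byrow = TRUE,
                      dimnames = list(c("c1", "c2", "c3"), c("T1", "T2"))))
}

random_clone_matrix <- function(n_clones = 20, n_types = 4) {
  m <- matrix(rpois(n_clones * n_types, 2), n_clones, n_types,
              dimnames = list(sprintf("c%03d", seq_len(n_clones)),
                              sprintf("T%d", seq_len(n_types))))
  m[rowSums(m) == 0, 1] <- 1L
  clone_matrix(m)
}
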