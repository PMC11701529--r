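test_that("NB test is symmetric, Poisson-limited and powered for 4-fold shifts", {
  y <- c(3L, 5L, 2L, 8L, 4L, 6L)
  r <- nb_test(y, y)
  expect_equal(r$log2fc, 0)
  expect_gt(r$p_value, 0.9)

  # swapping groups negates the fold change and keeps the p-value
  set.seed(51)
  a <- rnbinom(30, mu = 10, size = 2); b <- rnbinom(30, mu = 4, size = 2)
  r_ab <- nb_test(a, b); r_ba <- nb_test(b, a)
  expect_equal(r_ab$log2fc, -r_ba$log2fc)
  expect_equal(r_ab$p_value, r_ba$p_value, tolerance = 1e-6)

  # all-zero feature is reported but never significant
  z <- nb_test(rep(0L, 5), rep(0L, 5))
  expect_equal(z$p_value, 1)
  expect_equal(z$log2fc, 0)
  expect_error(nb_test(1:2, 1:5), "fewer than 3")

  # Poisson-like data: LRT p close to the Poisson GLM oracle
  set.seed(52)
  ok <- replicate(20, {
    ya <- rpois(100, 8); yb <- rpois(100, 8)
    p_nb <- nb_test(ya, yb)$p_value
    y <- c(ya, yb); g <- rep(0:1, each = 100)
    full <- glm(y ~ g, family = poisson())
    null <- glm(y ~ 1, family = poisson())
    p_pois <- pchisq(null$deviance - full$deviance, 1, lower.tail = FALSE)
    abs(p_nb - p_pois) <= 0.1 * max(p_pois, 0.01)
  })
  expect_gte(mean(ok), 0.9)

  # planted 4-fold change at n = 100/group is detected nearly always
  set.seed(53)
  hits <- replicate(50, {
    r <- nb_test(rnbinom(100, mu = 20, size = 2), rnbinom(100, mu = 5, size = 2))
    r$p_value < 0.05 && abs(r$log2fc) > 0.5
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Wilcoxon exact branch enumerates assignments; approx branch is close", {
  r <- wilcoxon_test(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_test(numeric(0), 1:3), "at least 2")

  set.seed(61)
  for (i in 1:60) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:4, na, TRUE); b <- sample(1:4, nb, TRUE)  # heavy ties
    expect_equal(wilcoxon_test(a, b)$p_value, oracle_wilcoxon(a, b))
  }

  # tie-free exact branch agrees with stats::wilcox.test exact
  set.seed(62)
  for (i in 1:20) {
    a <- sample(1:100, 5); b <- setdiff(sample(1:100, 12), a)[1:5]
    expect_equal(wilcoxon_test(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }

  # normal approximation within 0.01 of exact enumeration at n = 6 + 6
  set.seed(63)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    exact_p <- wilcoxon_test(a, b)$p_value
    approx_p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.05)
  }
})

make_diff_fixture <- function(seed = 71, n_per = 15, n_genes = 12) {
  set.seed(seed)
  clones <- data.frame(clone_id = c("clA", "clB"),
                       label = c("Ery biased", "Mono biased"))
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(2 * n_per)),
    cell_type = "HSPC",
    clone_id = rep(c("clA", "clB"), each = n_per))
  mu <- matrix(5, n_genes, 2 * n_per)
  mu[1, seq_len(n_per)] <- 40  # gene_01 up in the Ery-biased group
  vals <- matrix(rnbinom(length(mu), mu = mu, size = 5), n_genes)
  counts <- structure(list(
    values = methods::as(Matrix::Matrix(vals, sparse = TRUE),
                         "CsparseMatrix"),
    feature_ids = sprintf("gene_%02d", seq_len(n_genes)),
    cell_ids = cells$cell_id, modality = "rna"), class = "count_matrix")
  dimnames(counts$values) <- list(counts$feature_ids, counts$cell_ids)
  list(counts = counts, cells = cells, calls = clones)
}

test_that("fate_bias_diff ranks the truly different gene first", {
  fx <- make_diff_fixture()
  dr <- fate_bias_diff(fx$counts, fx$cells, fx$calls, "HSPC", "Ery", "Mono")
  expect_identical(dr$feature_id[1], "gene_01")
  expect_true(dr$significant[1])
  expect_gt(dr$log2_fold_change[1], 0.5)

  # impossible threshold: nothing significant
  dr0 <- fate_bias_diff(fx$counts, fx$cells, fx$calls, "HSPC", "Ery", "Mono",
                        p_cut = 0)
  expect_equal(sum(dr0$significant), 0L)

  # significance thresholds act as a monotone pure filter
  dr_loose <- fate_bias_diff(fx$counts, fx$cells, fx$calls, "HSPC",
                             "Ery", "Mono", p_cut = 0.2, lfc_cut = 0.1)
  expect_true(all(dr$feature_id[dr$significant] %in%
                    dr_loose$feature_id[dr_loose$significant]))

  # a group below the minimum size is a named error
  small <- fx$cells[-(1:13), ]
  expect_error(
    fate_bias_diff(fx$counts, small, fx$calls, "HSPC", "Ery", "Mono"),
    "'Ery'")

  # atac modality routes to the rank-sum test and still finds the gene
  fx$counts$modality <- "atac"
  dra <- fate_bias_diff(fx$counts, fx$cells, fx$calls, "HSPC", "Ery", "Mono")
  expect_identical(dra$feature_id[1], "gene_01")
})

test_that("planted DE genes are recovered with few false positives", {
  hits <- fp <- 0L
  for (seed in 1:10) {
    set.seed(seed + 400)
    n_per <- 30; n_genes <- 50; de <- 1:10
    mu <- matrix(8, n_genes, 2 * n_per)
    # |log2fc| = 2, half up in each group (as a fate-bias DE panel would be)
    mu[1:5, seq_len(n_per)] <- 8 * 2^2
    mu[6:10, n_per + seq_len(n_per)] <- 8 * 2^2
    vals <- matrix(rnbinom(length(mu), mu = mu, size = 2), n_genes)
    cells <- data.frame(cell_id = sprintf("c%03d", seq_len(2 * n_per)),
                        cell_type = "HSPC",
                        clone_id = rep(c("clA", "clB"), each = n_per))
    counts <- structure(list(
      values = methods::as(Matrix::Matrix(vals, sparse = TRUE),
                           "CsparseMatrix"),
      feature_ids = sprintf("g%02d", seq_len(n_genes)),
      cell_ids = cells$cell_id, modality = "rna"), class = "count_matrix")
    dimnames(counts$values) <- list(counts$feature_ids, counts$cell_ids)
    calls <- data.frame(clone_id = c("clA", "clB"),
                        label = c("Ery biased", "Mono biased"))
    dr <- fate_bias_diff(counts, cells, calls, "HSPC", "Ery", "Mono")
    sig <- dr$feature_id[dr$significant]
    hits <- hits + sum(sprintf("g%02d", de) %in% sig)
    fp <- fp + sum(!sig %in% sprintf("g%02d", de))
  }
  expect_gte(hits / 100, 0.9)   # 10 planted genes x 10 seeds
  expect_lte(fp / 10, 3)        # few false positives per seed on average
})

test_that("volcano table caps -log10 p and preserves fold-change signs", {
  dr <- data.frame(feature_id = c("a", "b", "c"),
                   log2_fold_change = c(2, -1.2, 0),
                   p_value = c(1e-300, 1, 0.01),
                   significant = c(TRUE, FALSE, FALSE))
  v <- volcano_table(dr)
  expect_equal(v$neg_log10_p, c(300, 0, 2))
  expect_equal(v$log2fc, c(2, -1.2, 0))
  expect_identical(v$significant, c(TRUE, FALSE, FALSE))
})
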