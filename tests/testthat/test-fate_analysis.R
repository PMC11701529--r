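test_that("fate mapping normalizes each clone row to fractions summing to 1", {
  cm <- clone_matrix(matrix(c(2L, 3L, 5L, 4L, 0L, 0L), 2, byrow = TRUE,
                            dimnames = list(c("a", "b"), c("X", "Y", "Z"))))
  fm <- fate_mapping(cm)
  expect_equal(unname(unclass(fm)[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(unclass(fm)[2, ]), c(1, 0, 0))

  # scale invariance: multiplying a clone row leaves its fate row unchanged
  cm2 <- clone_matrix(unclass(cm) * 7L)
  expect_equal(unclass(fate_mapping(cm2)), unclass(fm))

  set.seed(31)
  for (i in 1:25) {
    fmr <- fate_mapping(random_clone_matrix(40, 5))
    expect_equal(unname(rowSums(fmr)), rep(1, 40), tolerance = 1e-9)
    expect_true(all(fmr >= 0))
  }
})

test_that("one-sided Fisher matches hand-enumerated hypergeometric anchors", {
  expect_equal(fisher_exact_one_sided(3, 0, 0, 3)$p_value, 1 / 20)
  expect_equal(fisher_exact_one_sided(2, 2, 2, 2)$p_value, 53 / 70)
  expect_equal(fisher_exact_one_sided(0, 5, 3, 2)$p_value, 1)  # P(X >= 0)
  expect_equal(fisher_exact_one_sided(3, 0, 0, 3)$odds_ratio, Inf)
  expect_equal(fisher_exact_one_sided(2, 2, 2, 2)$odds_ratio, 1)
  expect_equal(fisher_exact_one_sided(0, 5, 3, 2)$odds_ratio, 0)
  expect_error(fisher_exact_one_sided(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_one_sided(1, -1, 2, 2), "non-negative")

  # two-sided option agrees with stats::fisher.test
  set.seed(8)
  for (i in 1:25) {
    tb <- rpois(4, 4); if (sum(tb[1:2]) == 0) tb[1] <- 1
    expect_equal(
      fisher_exact_one_sided(tb[1], tb[2], tb[3], tb[4],
                             alternative = "two.sided")$p_value,
      stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
      tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    # monotone in sorted-p order, permutation-equivariant
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("clone fate bias separates fully committed clones from balanced ones", {
  cm <- clone_matrix(matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE,
                            dimnames = list(c("cA", "cB"), c("T1", "T2"))))
  fb <- clone_fate_bias(cm)
  expect_equal(fb$tests$p_value[fb$tests$clone_id == "cA" &
                                  fb$tests$target_label == "T1"],
               1 / choose(20, 10))
  expect_identical(fb$calls$label, c("T1 biased", "T2 biased"))

  # a clone distributed exactly like the pooled background stays balanced
  bg <- clone_matrix(matrix(c(4L, 2L, 1L, 3L, 8L, 4L, 2L, 6L,
                              12L, 6L, 3L, 9L), 3, byrow = TRUE,
                            dimnames = list(paste0("c", 1:3), LETTERS[1:4])))
  # c1 matches the pooled composition of c2 + c3; enrichment is never strong
  fb2 <- clone_fate_bias(bg)
  c1 <- fb2$tests[fb2$tests$clone_id == "c1", ]
  expect_true(all(c1$p_value >= 0.5))
  expect_identical(fb2$calls$label[fb2$calls$clone_id == "c1"], "balanced")

  # impossible threshold: everything balanced
  fb3 <- clone_fate_bias(cm, alpha = 0)
  expect_true(all(fb3$calls$label == "balanced"))

  # size-1 clones are reported untested
  cm4 <- clone_matrix(matrix(c(1L, 0L, 5L, 5L), 2, byrow = TRUE,
                             dimnames = list(c("tiny", "big"), c("X", "Y"))))
  fb4 <- clone_fate_bias(cm4)
  expect_identical(fb4$calls$label[fb4$calls$clone_id == "tiny"], "untested")
  expect_true(is.na(fb4$calls$fdr[fb4$calls$clone_id == "tiny"]))

  # 2x2 table margins: a + b is the clone size, a + c the target total
  expect_true(all(fb$tests$a + fb$tests$b ==
                    rowSums(cm)[fb$tests$clone_id]))
  expect_error(clone_fate_bias(cm, targets = list(bad = "T9")), "absent")
})

test_that("named target sets pool lineages and stratified BH is available", {
  cm <- clone_matrix(matrix(c(8L, 7L, 1L, 0L, 2L, 2L, 6L, 6L), 2,
                            byrow = TRUE,
                            dimnames = list(c("lym", "mye"),
                                            c("T", "B", "Mono", "Neu"))))
  fb <- clone_fate_bias(cm, targets = list(Lymphoid = c("T", "B"),
                                           Myeloid = c("Mono", "Neu")))
  expect_identical(sort(unique(fb$tests$target_label)),
                   c("Lymphoid", "Myeloid"))
  expect_identical(fb$calls$label,
                   c("Lymphoid biased", "Myeloid biased"))
  fb_str <- clone_fate_bias(cm, targets = list(Lymphoid = c("T", "B"),
                                               Myeloid = c("Mono", "Neu")),
                            stratify_by_target = TRUE)
  for (tg in c("Lymphoid", "Myeloid")) {
    sel <- fb_str$tests$target_label == tg
    expect_equal(fb_str$tests$fdr[sel], bh_adjust(fb_str$tests$p_value[sel]))
  }
})

test_that("fate-bias summary fractions count clones or cells and sum to 1", {
  calls <- data.frame(clone_id = paste0("c", 1:4),
                      label = c("A biased", "A biased", "balanced", "B biased"),
                      a = c(9L, 9L, 1L, 1L), b = c(1L, 1L, 1L, 1L))
  s <- summarize_fate_bias(calls)
  expect_equal(s$fraction[s$label == "A biased"], 0.5)
  expect_equal(sum(s$fraction), 1)
  expect_equal(sum(s$n_clones), 4L)

  # cell weighting uses clone sizes
  sc <- summarize_fate_bias(calls, weight = "cell")
  expect_equal(sc$fraction[sc$label == "A biased"], 20 / 24)

  only_bal <- summarize_fate_bias(calls[3, , drop = FALSE])
  expect_identical(only_bal$label, "balanced")
  expect_equal(only_bal$fraction, 1)
  expect_error(summarize_fate_bias(calls, restrict_to = "cX"), "no fate-bias")
})
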