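test_that("deconvolution is exact on noiseless mixtures", {
  set.seed(6)
  sig <- make_signature(500, c("mesenchymal", "neuron", "glia",
                               "epithelial"))
  # identity mixture: a pure signature column
  est1 <- estimate_fractions(cbind(s = sig[, "neuron"]), sig)
  expect_equal(unname(est1$fractions[1, ]), c(0, 1, 0, 0),
               tolerance = 1e-9)

  f <- c(0.2, 0.3, 0.5, 0)
  bulk <- sig %*% f
  colnames(bulk) <- "s1"
  est2 <- estimate_fractions(bulk, sig)
  expect_equal(unname(est2$fractions[1, ]), f, tolerance = 1e-6)
  expect_equal(est2$mesenchymal_fraction[["s1"]], 0.2, tolerance = 1e-6)

  # per-sample scale invariance (library size cancels)
  est3 <- estimate_fractions(bulk * 37.5, sig)
  expect_equal(est3$fractions, est2$fractions, tolerance = 1e-9)

  # gene order must not matter
  perm <- sample(nrow(sig))
  est4 <- estimate_fractions(bulk[perm, , drop = FALSE], sig)
  expect_equal(est4$fractions, est2$fractions, tolerance = 1e-9)
})

test_that("exclusion filter and input validation are enforced", {
  set.seed(16)
  sig <- make_signature(80, c("mesenchymal", "neuron"))
  bulk <- sig %*% c(0.5, 0.5)
  colnames(bulk) <- "s"
  expect_error(estimate_fractions(bulk, sig,
                                  exclusion_list = rownames(sig)[1:40]),
               "fewer than 50")
  est <- estimate_fractions(bulk, sig,
                            exclusion_list = rownames(sig)[1:20])
  expect_identical(est$n_genes_used, 60L)
  expect_error(estimate_fractions(bulk * 0, sig), "all zero")
  expect_error(estimate_fractions(-bulk, sig), "non-negative")
})

test_that("noisy mixtures are recovered accurately at the cohort scale", {
  coh <- generate_cohort(cohort_config(seed = 31))  # noise_cv 0.1 default
  est <- estimate_fractions(coh$expression, coh$signature)
  mae <- mean(abs(est$mesenchymal_fraction -
                    coh$fractions[, "mesenchymal"]))
  expect_lt(mae, 0.05)
  expect_true(all(abs(rowSums(est$fractions) - 1) < 1e-6))

  # rank agreement between true and estimated mesenchymal content,
  # across independently generated cohorts
  for (s in 1:5) {
    ch <- generate_cohort(cohort_config(n_genes = 500L, seed = 100 + s))
    es <- estimate_fractions(ch$expression, ch$signature)
    rc <- rank_correlation(es$mesenchymal_fraction,
                           ch$fractions[, "mesenchymal"])
    expect_gt(rc$estimate, 0.9)
  }
})

test_that("coefficient of variation follows SD/mean x 100", {
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  expect_equal(cv_percent(rep(4, 6)), 0)
  expect_equal(cv_percent(c(1, 2, 3) * 1e4), 50)  # scale invariance
  expect_warning(cvna <- cv_percent(c(-1, 1)), "zero mean")
  expect_true(is.na(cvna))

  mc <- c(1, 2, 3, 10, 10, 10, 2, 4, 6)
  line <- rep(c("a", "b", "c"), each = 3)
  s <- cv_summary(mc, line)
  expect_equal(unname(s$per_line_cv), c(50, 0, 50))
  expect_equal(s$median_cv, 50)
  expect_equal(s$cv_range, c(0, 50))
  expect_equal(s$cv_of_line_means, cv_percent(c(2, 10, 4)))
  expect_error(cv_summary(1:3, c("a", "a", "b")), "at least 2")
})

test_that("Wilcoxon comparison is exact for small groups", {
  # fully separated 5 vs 5: the most extreme of C(10,5) rank splits
  r <- group_difference_test(c(1:5, 101:105), rep(c("a", "b"), each = 5))
  expect_equal(r$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(r$exact)
  expect_identical(r$higher_group, "b")

  # identical multisets: p = 1
  r2 <- group_difference_test(c(1, 2, 3, 1, 2, 3),
                              rep(c("a", "b"), each = 3))
  expect_false(r2$exact)  # ties force the corrected approximation
  r3 <- group_difference_test(c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6),
                              rep(c("a", "b"), 3))
  expect_true(r3$exact)

  # large groups switch to the normal approximation
  set.seed(41)
  r4 <- group_difference_test(rnorm(60), rep(c("a", "b"), 30))
  expect_false(r4$exact)
  expect_error(group_difference_test(1:5, rep("a", 5)), "two levels")
})

test_that("rank correlation matches hand ranks and the Pearson reference", {
  expect_equal(rank_correlation(1:7, (1:7)^3)$estimate, 1)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$estimate,
               0.8, tolerance = 1e-12)
  set.seed(51)
  x <- rnorm(25); y <- x + rnorm(25)
  rp <- rank_correlation(x, y, "pearson")
  ct <- cor.test(x, y)
  expect_equal(rp$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rp$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(rank_correlation(rep(1, 6), 1:6), "constant")
})

test_that("cohort composition statistics tie mesenchyme to size and quality", {
  coh <- generate_cohort(cohort_config(seed = 61))
  est <- estimate_fractions(coh$expression, coh$signature)
  st <- composition_stats(est$mesenchymal_fraction, coh$truth$line_id,
                          coh$truth$feret_um,
                          list(expert = coh$truth$expert_label))
  expect_gt(st$spearman_mc_feret$estimate, 0.5)
  expect_lt(st$group_tests$expert$p_value, 0.01)
  expect_identical(st$group_tests$expert$higher_group, "Low")
  expect_true(all(st$cv$per_line_cv >= 0))
})
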