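test_that("cohort configuration is validated", {
  expect_error(cohort_config(n_lines = 0), "configuration error")
  expect_error(cohort_config(high_quality_prob_per_line = rep(1.2, 12)),
               "probabilities")
  expect_error(cohort_config(feret_um_dist_high = c(-1, 0.1)),
               "configuration error")
  expect_error(cohort_config(cell_types = c("neuron", "astrocyte")),
               "mesenchymal")
})

test_that("quality classes follow the per-line prior", {
  all_high <- generate_cohort(fast_config(
    high_quality_prob_per_line = rep(1, 12)))
  expect_true(all(all_high$truth$true_quality == "High"))
  all_low <- generate_cohort(fast_config(
    high_quality_prob_per_line = rep(0, 12)))
  expect_true(all(all_low$truth$true_quality == "Low"))
})

test_that("mesenchymal link is constant without slope and noise", {
  coh <- generate_cohort(fast_config(mc_fraction_slope = 0,
                                     mc_noise_sd = 0))
  expect_equal(var(coh$truth$mc_fraction), 0)
})

test_that("default cohort couples mesenchymal fraction to Feret diameter", {
  coh <- generate_cohort(cohort_config())
  expect_identical(nrow(coh$truth), 72L)
  rc <- rank_correlation(coh$truth$mc_fraction, coh$truth$feret_um)
  expect_gt(rc$estimate, 0.5)
})

test_that("generated fraction vectors live on the unit simplex", {
  coh <- generate_cohort(fast_config(seed = 3))
  expect_true(all(abs(rowSums(coh$fractions) - 1) < 1e-9))
  expect_true(all(coh$fractions >= 0))
  # isodiametric consistency of the true features
  eq_diam <- sqrt(4 * coh$truth$area_um2 / pi)
  expect_true(all(coh$truth$feret_um >= eq_diam))
})

test_that("identical configurations generate identical cohorts", {
  c1 <- generate_cohort(fast_config(seed = 17))
  c2 <- generate_cohort(fast_config(seed = 17))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$expression, c2$expression)
  r1 <- render_organoid_image(c1$truth[4, ], c1$config)
  r2 <- render_organoid_image(c2$truth[4, ], c2$config)
  expect_identical(r1$image, r2$image)
})

test_that("rendered masks reproduce the true Feret and cyst count", {
  cfg <- fast_config(seed = 29)
  coh <- generate_cohort(cfg)
  for (i in seq_len(12)) {
    rr <- render_organoid_image(coh$truth[i, ], cfg)
    got <- section_feret(rr$mask, cfg$pixel_size_um)
    expect_lt(abs(got - coh$truth$feret_um[i]), 2 * cfg$pixel_size_um)
    n_gt <- sum(tabulate(as.integer(EBImage::bwlabel(rr$cyst_mask))) > 0)
    rec <- measure_organoid(rr$image, cfg$pixel_size_um)
    expect_identical(rec$cysts_count, as.integer(n_gt))
  }
})

test_that("circle render reproduces the requested diameter exactly", {
  cfg <- cohort_config(seed = 2)
  org <- list(organoid_id = "c", true_quality = "High", feret_um = 2000,
              cysts_count = 0L, render_seed = 5L)
  rr <- render_organoid_image(org, cfg, style = "circle")
  expect_lt(abs(section_feret(rr$mask, cfg$pixel_size_um) - 2000),
            2 * cfg$pixel_size_um)
})

test_that("requested cyst count appears in the ground-truth cyst mask", {
  cfg <- cohort_config(seed = 2)
  org <- list(organoid_id = "k3", true_quality = "Low", feret_um = 3800,
              cysts_count = 3L, render_seed = 8L)
  rr <- render_organoid_image(org, cfg)
  expect_identical(
    sum(tabulate(as.integer(EBImage::bwlabel(rr$cyst_mask))) > 0), 3L)
})

test_that("oversized organoids are refused by the renderer", {
  cfg <- cohort_config(image_shape = c(128L, 128L), seed = 2)
  org <- list(organoid_id = "big", true_quality = "Low", feret_um = 4000,
              cysts_count = 0L, render_seed = 1L)
  expect_error(render_organoid_image(org, cfg), "render error")
})

test_that("expression mixtures are exact without noise and calibrated with it", {
  set.seed(10)
  sig <- make_signature(400, c("mesenchymal", "neuron", "glia"))
  one_hot <- c(0, 1, 0)
  expect_equal(unname(generate_expression_mixture(one_hot, sig, 0)),
               unname(sig[, 2]))
  mix <- c(0.3, 0.7, 0)
  expect_equal(unname(generate_expression_mixture(mix, sig, 0)),
               unname(0.3 * sig[, 1] + 0.7 * sig[, 2]))
  expect_error(generate_expression_mixture(c(-0.1, 1.1, 0), sig, 0),
               "negative")
  expect_error(generate_expression_mixture(c(1, 0), sig, 0), "length")

  # multiplicative noise has the requested coefficient of variation
  sig2k <- make_signature(2000, c("mesenchymal", "neuron"), seed = 4)
  f <- c(0.4, 0.6)
  clean <- generate_expression_mixture(f, sig2k, 0)
  noisy <- generate_expression_mixture(f, sig2k, 0.1, seed = 9)
  rel <- noisy / clean
  expect_lt(abs(sd(rel) / mean(rel) - 0.10), 0.02)
})

test_that("fluorescence panel reflects the mesenchymal coupling", {
  coh <- generate_cohort(fast_config(seed = 13))
  # zero noise, equal slopes: both markers are the same monotone map of MC
  fl0 <- generate_fluorescence_panel(coh, coupling = c(CD73 = 100,
                                                       CD105 = 100,
                                                       MAP2 = -50),
                                     noise_sd = 0, seed = 1)
  expect_equal(rank_correlation(fl0$CD73, fl0$CD105)$estimate, 1)

  # zero slope: association with size collapses to noise
  fln <- generate_fluorescence_panel(coh, coupling = c(CD73 = 0,
                                                       CD105 = 0,
                                                       MAP2 = 0),
                                     noise_sd = 8, seed = 2)
  expect_lt(abs(rank_correlation(fln$CD105,
                                 coh$truth$feret_um)$estimate), 0.3)

  # default coupling: positive marker-size correlation
  fl <- generate_fluorescence_panel(coh, seed = 3)
  expect_gt(rank_correlation(fl$CD105, fl$section_feret_um)$estimate, 0)
  expect_gt(rank_correlation(fl$CD73, fl$CD105)$estimate, 0)
})

test_that("cohorts write to disk as plain-text bundles", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(fast_config(seed = 19))
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("truth.csv", "fractions.csv", "expression.csv", "signature.csv",
      "cohort.cfg")))))
  tr <- read_feature_table(file.path(dir, "truth.csv"))
  expect_equal(tr$feret_um, coh$truth$feret_um, tolerance = 1e-8)
  cfg <- read_flat_config(file.path(dir, "cohort.cfg"))
  expect_equal(cfg$seed, 19)
  expr <- read_expression_table(file.path(dir, "expression.csv"))
  expect_equal(unname(expr), unname(coh$expression), tolerance = 1e-8)
})
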