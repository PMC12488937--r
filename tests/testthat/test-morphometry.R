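test_that("segmentation recovers a synthetic disc and rejects degenerate input", {
  expect_error(segment_organoid(matrix(128, 50, 50), 1),
               "uniform|empty")

  img <- disc_image(60)
  mask <- segment_organoid(img, pixel_size_um = 1)
  expect_s3_class(mask, "organoid_mask")
  expect_lt(abs(sum(mask$mask) - pi * 60^2) / (pi * 60^2), 0.01)

  # cystic organoid: bright interior discs must not punch holes
  img2 <- disc_image(60, cysts = list(c(-20, 0, 12), c(25, 10, 10)))
  m2 <- segment_organoid(img2, 1)
  lab <- EBImage::bwlabel(m2$mask)
  expect_identical(max(as.integer(lab)), 1L)
  expect_lt(abs(sum(m2$mask) - pi * 60^2) / (pi * 60^2), 0.01)

  # organoid cropped by the field of view raises the border flag
  img3 <- matrix(200, 60, 60); img3[, 1:40] <- 80
  expect_warning(m3 <- segment_organoid(img3, 1), "border")
  expect_true(m3$border_warning)
})

test_that("shape measurement matches analytic geometry", {
  tri <- triangle_mask(300, 400)
  rec <- measure_shape(tri, pixel_size_um = 1)
  expect_lt(abs(rec$feret_um - 500), 2)

  rec_d <- measure_shape(disc_mask(80), pixel_size_um = 1)
  expect_lt(abs(rec_d$area_um2 - pi * 80^2) / (pi * 80^2), 0.01)
  expect_gt(rec_d$circularity, 0.97)
  expect_gt(rec_d$solidity, 0.97)
  expect_lt(abs(rec_d$aspect_ratio - 1), 0.03)
  expect_lt(abs(rec_d$roundness - 1), 0.03)
  expect_lt(abs(rec_d$feret_um - 160), 2)

  expect_error(measure_shape(matrix(FALSE, 5, 5), 1), "fewer than 3")
})

test_that("rotating-calipers Feret equals the brute-force pairwise maximum", {
  set.seed(42)
  for (i in 1:60) {
    m <- blob_mask(radius = runif(1, 8, 22))
    rec <- measure_shape(m, pixel_size_um = 1)
    expect_equal(rec$feret_um, brute_force_feret(m), tolerance = 1e-12)
  }
  # non-star-convex shapes: unions of offset discs
  for (i in 1:20) {
    m <- disc_mask(12, pad = 20)
    sh <- sample(4:10, 2)
    m <- m | rbind(m[-seq_len(sh[1]), ], matrix(FALSE, sh[1], ncol(m)))
    m <- m | cbind(m[, -seq_len(sh[2])], matrix(FALSE, nrow(m), sh[2]))
    rec <- measure_shape(m, pixel_size_um = 1)
    expect_equal(rec$feret_um, brute_force_feret(m), tolerance = 1e-12)
  }
})

test_that("measurements scale with pixel size and are rotation invariant", {
  set.seed(7)
  m <- blob_mask(radius = 16)
  r1 <- measure_shape(m, pixel_size_um = 1)
  r2 <- measure_shape(m, pixel_size_um = 2)
  expect_equal(r2$feret_um, 2 * r1$feret_um)
  expect_equal(r2$perimeter_um, 2 * r1$perimeter_um)
  expect_equal(r2$area_um2, 4 * r1$area_um2)
  for (f in c("aspect_ratio", "circularity", "roundness", "solidity"))
    expect_equal(r2[[f]], r1[[f]])

  amps <- runif(4, 0, 0.1); phases <- runif(4, 0, 2 * pi)
  base <- measure_shape(blob_mask(20, 96, 0, amps, phases), 1)$feret_um
  for (phi in c(0.3, 1.1, 2.5)) {
    rot <- measure_shape(blob_mask(20, 96, phi, amps, phases), 1)$feret_um
    expect_lt(abs(rot - base), 1)
  }
})

test_that("isodiametric inequality holds for measured blobs", {
  set.seed(99)
  for (i in 1:30) {
    m <- blob_mask(radius = runif(1, 8, 22))
    rec <- measure_shape(m, pixel_size_um = 1)
    expect_lte(rec$area_um2, pi * rec$feret_um^2 / 4)
  }
})

test_that("cyst detection counts and sizes interior bright regions", {
  expect_error(detect_cysts(disc_image(50), disc_mask(50),
                            min_cyst_area_um2 = 0, pixel_size_um = 1),
               "positive")

  # cyst-free organoid
  img <- disc_image(60)
  mask <- segment_organoid(img, 1)
  cy <- detect_cysts(img, mask)
  expect_identical(cy$cysts_count, 0L)
  expect_identical(cy$cysts_area_ratio, 0)

  # three well-separated discs
  img3 <- disc_image(80, cysts = list(c(-35, 0, 14), c(30, 30, 12),
                                      c(25, -35, 13)), pad = 10)
  m3 <- segment_organoid(img3, 1)
  cy3 <- detect_cysts(img3, m3, min_cyst_area_um2 = 100)
  expect_equal(cy3$cysts_count, 3)

  # one disc with 10% of the organoid area
  rc <- round(sqrt(0.10) * 100)
  img1 <- disc_image(100, cysts = list(c(0, 0, rc)), pad = 10)
  m1 <- segment_organoid(img1, 1)
  cy1 <- detect_cysts(img1, m1, min_cyst_area_um2 = 100)
  expect_equal(cy1$cysts_count, 1)
  expect_lt(abs(cy1$cysts_area_ratio - 0.10), 0.01)
})

test_that("fluorescence intensity measures follow their definitions", {
  img <- matrix(0, 40, 40)
  m <- matrix(FALSE, 40, 40); m[10:20, 10:20] <- TRUE
  bg <- matrix(FALSE, 40, 40); bg[30:38, 30:38] <- TRUE

  # plug-in arithmetic: IntDen 1000 over 10 px, background mean 5
  m10 <- matrix(FALSE, 40, 40); m10[10, 10:19] <- TRUE
  img10 <- img; img10[m10] <- 100; img10[bg] <- 5
  r <- corrected_fluorescence_intensity(img10, m10, bg)
  expect_equal(r$integrated_density, 1000)
  expect_equal(r$cfi, 1000 - 10 * 5)
  expect_equal(r$cfi_per_area, 95)

  # zero background: CFI equals the integrated density
  imgz <- img; imgz[m] <- 7
  rz <- corrected_fluorescence_intensity(imgz, m, bg)
  expect_equal(rz$cfi, rz$integrated_density)

  # constant image cancels exactly
  rc <- corrected_fluorescence_intensity(matrix(11, 40, 40), m, bg)
  expect_equal(rc$cfi, 0)

  expect_error(corrected_fluorescence_intensity(img, m, img * 0 > 1),
               "empty background")
  expect_error(corrected_fluorescence_intensity(img, m, m), "overlap")

  # MFI: constant field, masking invariance
  expect_equal(mean_fluorescence_intensity(imgz, m), 7)
  imgn <- imgz; imgn[!m] <- runif(sum(!m), 0, 255)
  expect_equal(mean_fluorescence_intensity(imgn, m), 7)

  # section Feret equals the brute-force pairwise maximum
  set.seed(3)
  sm <- blob_mask(radius = 14)
  expect_equal(section_feret(sm, 2), 2 * brute_force_feret(sm),
               tolerance = 1e-12)
})

test_that("image IO round-trips through TIFF", {
  dir <- withr::local_tempdir()
  cfg <- fast_config(seed = 5)
  coh <- generate_cohort(cfg)
  rr <- render_organoid_image(coh$truth[1, ], cfg)
  p <- file.path(dir, "o1.tif")
  EBImage::writeImage(EBImage::Image(rr$image / 255), p,
                      bits.per.sample = 8L)
  img <- read_organoid_image(p)
  expect_equal(dim(img), dim(rr$image))
  expect_equal(round(img * 255), rr$image, tolerance = 1e-8)
  rec <- measure_organoid(img, cfg$pixel_size_um)
  expect_lt(abs(rec$feret_um - coh$truth$feret_um[1]),
            2 * cfg$pixel_size_um)
})
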