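#' Configuration of a synthetic organoid cohort
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' Defaults emulate a 12-line x 6-organoid day-30 brain-organoid study
#' with two latent quality classes: High-quality organoids are smaller,
#' rounder, budding and nearly cyst-free; Low-quality organoids are
#' larger, irregular and cystic. The latent mesenchymal-cell fraction is
#' coupled to the Feret diameter through a logit-linear link so that
#' larger organoids carry more mesenchyme.
#'
#' @param n_lines Number of stem-cell lines.
#' @param organoids_per_line Organoids sampled per line.
#' @param high_quality_prob_per_line Probability that an organoid of each
#'   line is High quality (length `n_lines`, recycled from length-1);
#'   defaults alternate good, intermediate and poor lines.
#' @param feret_um_dist_high,feret_um_dist_low Lognormal Feret-diameter
#'   distribution per class: `c(median_um, log_sd)`.
#' @param cyst_count_dist_high,cyst_count_dist_low Poisson mean cyst
#'   count per class.
#' @param mc_fraction_intercept,mc_fraction_slope Intercept and slope
#'   (per µm Feret) of the logit-linear mesenchymal-fraction model.
#' @param mc_noise_sd SD of the logit-scale noise on the mesenchymal
#'   fraction.
#' @param pixel_size_um Pixel size of rendered images, µm/px.
#' @param image_shape Raster size in pixels, `c(nx, ny)`.
#' @param expression_noise_cv Coefficient of variation of the
#'   multiplicative per-gene noise on expression mixtures.
#' @param n_genes,cell_types Size and cell-type names of the generated
#'   signature matrix; must include `"mesenchymal"`.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return An object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_lines = 12L,
                          organoids_per_line = 6L,
                          high_quality_prob_per_line =
                            rep(c(0.9, 0.75, 0.5, 0.3), length.out = n_lines),
                          feret_um_dist_high = c(median_um = 2400, log_sd = 0.15),
                          feret_um_dist_low = c(median_um = 3800, log_sd = 0.15),
                          cyst_count_dist_high = 0.4,
                          cyst_count_dist_low = 3.5,
                          mc_fraction_intercept = -5.5,
                          mc_fraction_slope = 0.0013,
                          mc_noise_sd = 1.0,
                          pixel_size_um = 10,
                          image_shape = c(768L, 768L),
                          expression_noise_cv = 0.1,
                          n_genes = 2000L,
                          cell_types = c("mesenchymal", "neuron",
                                         "neural_progenitor", "radial_glia",
                                         "astrocyte", "opc",
                                         "choroid_plexus", "neural_crest",
                                         "epithelial", "microglia_like"),
                          seed = 111L) {
  cfg <- list(n_lines = as.integer(n_lines),
              organoids_per_line = as.integer(organoids_per_line),
              high_quality_prob_per_line =
                rep(high_quality_prob_per_line, length.out = n_lines),
              feret_um_dist_high = feret_um_dist_high,
              feret_um_dist_low = feret_um_dist_low,
              cyst_count_dist_high = cyst_count_dist_high,
              cyst_count_dist_low = cyst_count_dist_low,
              mc_fraction_intercept = mc_fraction_intercept,
              mc_fraction_slope = mc_fraction_slope,
              mc_noise_sd = mc_noise_sd,
              pixel_size_um = pixel_size_um,
              image_shape = as.integer(image_shape),
              expression_noise_cv = expression_noise_cv,
              n_genes = as.integer(n_genes),
              cell_types = cell_types,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  err <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$n_lines < 1L || cfg$organoids_per_line < 1L)
    err("counts must be positive")
  p <- cfg$high_quality_prob_per_line
  if (length(p) != cfg$n_lines || any(p < 0) || any(p > 1))
    err("high_quality_prob_per_line must be probabilities, one per line")
  for (nm in c("feret_um_dist_high", "feret_um_dist_low")) {
    d <- cfg[[nm]]
    if (length(d) != 2L || any(d <= 0)) err(nm, " must be c(median_um > 0, log_sd > 0)")
  }
  if (cfg$cyst_count_dist_high < 0 || cfg$cyst_count_dist_low < 0)
    err("Poisson cyst means must be non-negative")
  if (cfg$mc_noise_sd < 0 || cfg$expression_noise_cv < 0)
    err("noise parameters must be non-negative")
  if (cfg$pixel_size_um <= 0) err("pixel_size_um must be positive")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 16L))
    err("image_shape must be two pixel counts >= 16")
  if (cfg$n_genes < 10L) err("n_genes must be at least 10")
  if (!"mesenchymal" %in% cfg$cell_types)
    err("cell_types must include 'mesenchymal'")
  if (is.na(cfg$seed)) err("seed is mandatory")
  invisible(cfg)
}

#' Generate a cell-type signature matrix
#'
#' Lognormal baseline expression with a disjoint block of marker genes
#' (8-fold up) per cell type; used as the reference for deconvolution of
#' synthetic mixtures.
#'
#' @param n_genes Number of genes.
#' @param cell_types Character vector of cell-type names.
#' @param markers_per_type Number of marker genes per type (default 4% of
#'   genes, at least 5).
#' @param seed Optional seed (uses current RNG stream when `NULL`).
#' @return Non-negative genes x cell-types matrix with dimnames.
#' @export
make_signature <- function(n_genes, cell_types, markers_per_type = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(cell_types)
  if (is.null(markers_per_type))
    markers_per_type <- max(5L, floor(0.04 * n_genes))
  base <- rlnorm(n_genes, meanlog = log(50), sdlog = 1)
  sig <- vapply(seq_len(k), function(j) base * rlnorm(n_genes, 0, 0.3),
                numeric(n_genes))
  marker_pool <- sample.int(n_genes)
  for (j in seq_len(k)) {
    i0 <- (j - 1L) * markers_per_type
    if (i0 + markers_per_type <= n_genes) {
      idx <- marker_pool[(i0 + 1L):(i0 + markers_per_type)]
      sig[idx, j] <- sig[idx, j] * 8
    }
  }
  dimnames(sig) <- list(sprintf("gene%05d", seq_len(n_genes)), cell_types)
  sig
}

#' Generate a synthetic organoid cohort with known ground truth
#'
#' Draws, for every organoid, a latent quality class from the per-line
#' prior, the nine morphological parameters from class-conditional
#' distributions, a mesenchymal fraction from the logit-linear size link
#' (remaining mass split across the other cell types), and a bulk
#' expression profile as a noisy linear mixture of the signature columns.
#' The whole cohort is a deterministic function of the configuration.
#'
#' @param config A [cohort_config()].
#' @return Object of class `organoid_cohort`: list with `truth` (one row
#'   per organoid: ids, `true_quality`, `expert_label`, the nine feature
#'   columns, `mc_fraction`, `render_seed`), `fractions` (organoids x
#'   cell types, rows sum to 1), `signature` (genes x cell types),
#'   `expression` (genes x organoids) and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_lines * config$organoids_per_line
  line <- rep(seq_len(config$n_lines), each = config$organoids_per_line)
  line_id <- sprintf("line%02d", line)
  organoid_id <- sprintf("L%02d_O%d", line,
                         rep(seq_len(config$organoids_per_line),
                             config$n_lines))
  p_high <- config$high_quality_prob_per_line[line]
  high <- runif(n) < p_high
  quality <- ifelse(high, "High", "Low")

  fd <- ifelse(high, config$feret_um_dist_high[1], config$feret_um_dist_low[1])
  fs <- ifelse(high, config$feret_um_dist_high[2], config$feret_um_dist_low[2])
  feret <- rlnorm(n, meanlog = log(fd), sdlog = fs)

  # shape factor sf = area / (pi/4 feret^2) and boundary roughness
  # rough = perimeter / (pi feret); the class effect on both is kept mild
  # so pure shape descriptors stay weak predictors, as in real cohorts
  sf <- pmin(0.97, ifelse(high, 0.79, 0.76) * exp(rnorm(n, 0, 0.18)))
  rough <- ifelse(high, 1.16, 1.22) * exp(rnorm(n, 0, 0.15))
  rough <- pmax(rough, sqrt(sf) * 1.01)      # keeps circularity below 1
  area <- pi / 4 * feret^2 * sf
  perim <- pi * feret * rough
  aspect <- 1 + abs(rnorm(n, 0, ifelse(high, 0.07, 0.11)))
  circ <- sf / rough^2
  round_ <- pmin(1, sf / aspect * exp(rnorm(n, 0, 0.05)))
  solidity <- plogis(rnorm(n, ifelse(high, 3.0, 2.7), 0.6))

  lam <- ifelse(high, config$cyst_count_dist_high, config$cyst_count_dist_low)
  cysts <- rpois(n, lam)
  cyst_ratio <- vapply(seq_len(n), function(i) {
    if (cysts[i] == 0L) return(0)
    min(0.5, sum(rbeta(cysts[i], 2, 30)))
  }, numeric(1))

  eta <- config$mc_fraction_intercept + config$mc_fraction_slope * feret +
    rnorm(n, 0, config$mc_noise_sd)
  mc <- plogis(eta)

  k <- length(config$cell_types)
  base_w <- c(0.30, 0.22, 0.16, 0.10, 0.06, 0.05, 0.04, 0.04, 0.03)
  base_w <- rep(base_w, length.out = k - 1L)
  fractions <- matrix(0, n, k,
                      dimnames = list(organoid_id, config$cell_types))
  mc_col <- match("mesenchymal", config$cell_types)
  for (i in seq_len(n)) {
    w <- base_w * rgamma(k - 1L, shape = 8, rate = 8)
    fractions[i, -mc_col] <- (1 - mc[i]) * w / sum(w)
    fractions[i, mc_col] <- mc[i]
  }

  signature <- make_signature(config$n_genes, config$cell_types)
  expression <- vapply(seq_len(n), function(i) {
    generate_expression_mixture(fractions[i, ], signature,
                                noise_cv = config$expression_noise_cv)
  }, numeric(config$n_genes))
  dimnames(expression) <- list(rownames(signature), organoid_id)

  render_seed <- sample.int(.Machine$integer.max - 1L, n)

  truth <- data.frame(
    organoid_id = organoid_id, line_id = line_id,
    true_quality = quality, expert_label = quality,
    feret_um = feret, area_um2 = area, perimeter_um = perim,
    aspect_ratio = aspect, circularity = circ, roundness = round_,
    solidity = solidity, cysts_count = cysts,
    cysts_area_ratio = cyst_ratio, mc_fraction = mc,
    render_seed = render_seed, stringsAsFactors = FALSE
  )
  structure(list(truth = truth, fractions = fractions,
                 signature = signature, expression = expression,
                 config = config),
            class = "organoid_cohort")
}

#' @export
print.organoid_cohort <- function(x, ...) {
  cat("Synthetic organoid cohort:", nrow(x$truth), "organoids,",
      x$config$n_lines, "lines\n")
  cat("  quality: ", sum(x$truth$true_quality == "High"), " High / ",
      sum(x$truth$true_quality == "Low"), " Low\n", sep = "")
  cat("  expression:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;",
      ncol(x$fractions), "cell types\n")
  invisible(x)
}

#' Render a synthetic brightfield image of one organoid
#'
#' Draws a dark star-convex blob on a light background whose maximal
#' caliper diameter matches the organoid's true Feret diameter (the
#' boundary polygon is rescaled to the target before rasterization, so
#' the rendered mask reproduces it within about 2 px). Low-quality
#' organoids get low-order boundary irregularity and `cysts_count` bright
#' interior discs; High-quality organoids get small peripheral buds.
#'
#' @param organoid One row of a cohort `truth` table (or an equivalent
#'   list with `feret_um`, `true_quality`, `cysts_count`, `render_seed`,
#'   `organoid_id`).
#' @param config The [cohort_config()] of the cohort (pixel size, canvas).
#' @param style `"auto"` (class-dependent boundary, default) or
#'   `"circle"` (exact disc, for calibration checks).
#' @return Object of class `organoid_render`: list with `image` (8-bit
#'   values, light background), `mask` and `cyst_mask` (logical
#'   ground-truth rasters), `feret_px_true` and `organoid_id`.
#' @export
render_organoid_image <- function(organoid, config,
                                  style = c("auto", "circle")) {
  style <- match.arg(style)
  organoid <- as.list(organoid)
  set.seed(organoid$render_seed %||% config$seed)
  feret_px <- organoid$feret_um / config$pixel_size_um
  nx <- config$image_shape[1]; ny <- config$image_shape[2]

  theta <- seq(-pi, pi, length.out = 721L)[-721L]
  r <- rep(1, length(theta))
  if (style == "auto") {
    if (identical(organoid$true_quality, "Low")) {
      for (m in 2:5)
        r <- r + runif(1, 0.03, 0.09) * cos(m * theta + runif(1, 0, 2 * pi))
    } else {
      n_bud <- sample(4:7, 1)
      ang <- runif(n_bud, -pi, pi)
      amp <- runif(n_bud, 0.03, 0.07)
      for (b in seq_len(n_bud)) {
        d <- atan2(sin(theta - ang[b]), cos(theta - ang[b]))
        r <- r + amp[b] * exp(-(d / 0.12)^2 / 2)
      }
    }
    r <- pmax(r, 0.25)
  }
  pts <- cbind(r * cos(theta), r * sin(theta))
  scale <- feret_px / feret_diameter(pts)
  r_px <- r * scale
  if (2 * max(r_px) + 8 > min(nx, ny))
    stop("render error: organoid larger than canvas")

  cx <- nx / 2; cy <- ny / 2
  px <- matrix(seq_len(nx), nx, ny) - cx
  py <- matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy
  rad <- sqrt(px^2 + py^2)
  ang <- atan2(py, px)
  # periodic linear interpolation of the boundary radius
  bound <- approx(c(theta, pi), c(r_px, r_px[1]), xout = ang,
                  rule = 2)$y
  mask <- rad <= bound

  cyst_mask <- matrix(FALSE, nx, ny)
  k <- organoid$cysts_count %||% 0L
  if (style == "auto" && k > 0L) {
    r_min <- min(r_px)
    placed <- matrix(numeric(0), 0, 3)  # x, y, radius
    for (ci in seq_len(k)) {
      cr <- runif(1, 12, min(28, max(13, r_min / 3)))
      ok <- FALSE
      for (try in 1:300) {
        a <- runif(1, -pi, pi)
        d <- runif(1, 0, max(0, r_min - cr - 6))
        x0 <- d * cos(a); y0 <- d * sin(a)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - x0)^2 + (placed[, 2] - y0)^2) >
                placed[, 3] + cr + 8)) { ok <- TRUE; break }
      }
      if (!ok) { cr <- cr / 2; x0 <- 0; y0 <- 0 }
      placed <- rbind(placed, c(x0, y0, cr))
      cyst_mask <- cyst_mask | ((px - x0)^2 + (py - y0)^2 <= cr^2)
    }
    cyst_mask <- cyst_mask & mask
  }

  img <- matrix(200, nx, ny)
  img[mask] <- 80
  img[cyst_mask] <- 170
  img <- img + rnorm(length(img), 0, 2)
  img <- to_uint8(img)
  structure(list(image = img, mask = mask, cyst_mask = cyst_mask,
                 feret_px_true = feret_px,
                 organoid_id = organoid$organoid_id %||% NA_character_),
            class = "organoid_render")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize a bulk expression profile from cell-type fractions
#'
#' Computes the linear mixture `signature %*% fractions` and multiplies
#' each gene by i.i.d. gamma noise with unit mean and the requested
#' coefficient of variation (`noise_cv = 0` returns the exact mixture).
#'
#' @param fractions Non-negative vector, one entry per signature column.
#' @param signature Non-negative genes x cell-types matrix.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return Numeric per-gene expression vector.
#' @export
generate_expression_mixture <- function(fractions, signature, noise_cv = 0,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fractions <- as.numeric(fractions)
  if (any(fractions < 0)) stop("domain error: negative fractions")
  if (length(fractions) != ncol(signature))
    stop("fractions length must equal the signature column count")
  if (any(signature < 0)) stop("signature must be non-negative")
  x <- as.vector(signature %*% fractions)
  if (noise_cv > 0) {
    shp <- 1 / noise_cv^2
    x <- x * rgamma(length(x), shape = shp, rate = shp)
  }
  names(x) <- rownames(signature)
  x
}

#' Simulate a per-organoid immunofluorescence panel
#'
#' Per organoid and channel, the mean fluorescence intensity is
#' `baseline + coupling * mc_fraction + noise`; positive coupling on the
#' two mesenchymal surface markers (CD73, CD105) induces their mutual
#' correlation and their correlation with organoid size. A section Feret
#' diameter (a single cryosection through the organoid, smaller and
#' noisier than the whole-mount maximum) is simulated alongside.
#'
#' @param cohort An `organoid_cohort`.
#' @param coupling Named slopes (MFI units per unit mesenchymal fraction)
#'   for channels `CD73`, `CD105`, `MAP2`.
#' @param baseline Named channel baselines (MFI units).
#' @param noise_sd SD of additive MFI noise.
#' @param section_scale,section_log_sd Median ratio and log-SD of
#'   section Feret to whole-organoid Feret.
#' @param seed Optional seed.
#' @return `data.frame` with `organoid_id`, `line_id`, one MFI column per
#'   channel, and `section_feret_um`.
#' @export
generate_fluorescence_panel <- function(cohort,
                                        coupling = c(CD73 = 150, CD105 = 150,
                                                     MAP2 = -80),
                                        baseline = c(CD73 = 30, CD105 = 30,
                                                     MAP2 = 130),
                                        noise_sd = 8,
                                        section_scale = 0.7,
                                        section_log_sd = 0.12,
                                        seed = NULL) {
  stopifnot(inherits(cohort, "organoid_cohort"))
  if (any(!is.finite(coupling))) stop("coupling slopes must be finite")
  if (!is.null(seed)) set.seed(seed)
  tr <- cohort$truth
  n <- nrow(tr)
  out <- data.frame(organoid_id = tr$organoid_id, line_id = tr$line_id,
                    stringsAsFactors = FALSE)
  for (ch in names(coupling)) {
    out[[ch]] <- pmax(0, baseline[[ch]] + coupling[[ch]] * tr$mc_fraction +
                        rnorm(n, 0, noise_sd))
  }
  out$section_feret_um <- tr$feret_um * section_scale *
    exp(rnorm(n, 0, section_log_sd))
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes `truth.csv`, `fractions.csv`, `expression.csv` (genes as rows),
#' `signature.csv` and `cohort.cfg` (flat `key = value` text) into a
#' directory; optionally renders and writes 8-bit TIFF images under
#' `images/`.
#'
#' @param cohort An `organoid_cohort`.
#' @param dir Output directory (created if needed).
#' @param render Also render and write brightfield images (default FALSE).
#' @return Invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir, render = FALSE) {
  stopifnot(inherits(cohort, "organoid_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(data.frame(organoid_id = rownames(cohort$fractions),
                       cohort$fractions, check.names = FALSE),
            file.path(dir, "fractions.csv"), row.names = FALSE)
  write.csv(data.frame(gene_id = rownames(cohort$expression),
                       cohort$expression, check.names = FALSE),
            file.path(dir, "expression.csv"), row.names = FALSE)
  write.csv(data.frame(gene_id = rownames(cohort$signature),
                       cohort$signature, check.names = FALSE),
            file.path(dir, "signature.csv"), row.names = FALSE)
  write_flat_config(cohort$config, file.path(dir, "cohort.cfg"))
  if (render) {
    imdir <- file.path(dir, "images")
    dir.create(imdir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort$truth))) {
      rr <- render_organoid_image(cohort$truth[i, ], cohort$config)
      EBImage::writeImage(EBImage::Image(rr$image / 255),
                          file.path(imdir, paste0(rr$organoid_id, ".tif")),
                          bits.per.sample = 8L)
    }
  }
  invisible(dir)
}
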