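#' Segment a single organoid from a brightfield image
#'
#' Converts the image to 8-bit, applies a global Otsu threshold (optionally
#' shifted by `offset`), keeps the largest connected component
#' (8-connectivity) and fills interior holes, so that translucent cysts do
#' not punch holes into the organoid mask.
#'
#' @param image Numeric matrix (grayscale). Values in \[0, 1\] or \[0, 255\].
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @param polarity `"dark"` (default, brightfield: organoid darker than
#'   background) or `"bright"`.
#' @param offset Additive shift of the automatic threshold on the \[0, 1\]
#'   intensity scale; stands in for the manual fine-tuning an operator
#'   would do.
#' @param id Optional identifier stored in the result.
#' @return An object of class `organoid_mask`: list with `mask` (logical
#'   matrix), `pixel_size_um`, `threshold` (on the 0-255 scale), `id` and
#'   `border_warning` (TRUE when at least half of the image border is
#'   foreground, i.e. the organoid is likely cropped).
#' @export
segment_organoid <- function(image, pixel_size_um,
                             polarity = c("dark", "bright"),
                             offset = 0, id = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  img8 <- to_uint8(image)
  if (var(as.vector(img8)) == 0)
    stop("segmentation error: image is uniform, no foreground found")
  thr <- EBImage::otsu(EBImage::Image(img8 / 255), range = c(0, 1),
                       levels = 256) + offset
  fg <- if (polarity == "dark") img8 / 255 < thr else img8 / 255 > thr
  if (!any(fg)) stop("segmentation error: empty foreground")
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(as.integer(lab))
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask) > 0
  border <- c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)])
  border_warning <- mean(border) >= 0.5
  if (border_warning)
    warning("foreground touches >= 50% of the image border; ",
            "organoid may be cropped")
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 threshold = thr * 255, id = id,
                 border_warning = border_warning),
            class = "organoid_mask")
}

# rescale/round any grayscale matrix to integers on [0, 255]
to_uint8 <- function(image) {
  rng <- range(image)
  if (rng[2] <= 1 && rng[1] >= 0) image <- image * 255
  image <- round(image)
  image[image < 0] <- 0
  image[image > 255] <- 255
  image
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "organoid_mask")) mask$mask
  else if (is.matrix(mask)) mask > 0
  else stop("`mask` must be an `organoid_mask` or a matrix")
}

mask_pixel_size <- function(mask, pixel_size_um) {
  if (!is.null(pixel_size_um)) return(pixel_size_um)
  if (inherits(mask, "organoid_mask")) return(mask$pixel_size_um)
  stop("`pixel_size_um` is required when `mask` is a plain matrix")
}

# ordered boundary-pixel centers (one closed contour) of a binary mask
mask_contour <- function(m) {
  oc <- EBImage::ocontour(EBImage::Image(m * 1))
  if (length(oc) == 0L) stop("measurement error: empty mask")
  ctr <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  storage.mode(ctr) <- "double"
  ctr
}

# every foreground pixel with a 4-neighbour background (or image edge);
# complete by construction, unlike a single traced contour
boundary_pixels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(m & !core, arr.ind = TRUE)
}

# corner-corrected length of the closed 8-connected boundary chain
# (Kulpa weights: 0.948 per axial, 1.340 per diagonal step), a standard
# estimator that is asymptotically unbiased on smooth outlines
chain_perimeter <- function(ctr) {
  n <- nrow(ctr)
  if (n < 2L) return(0)
  steps <- abs(diff(rbind(ctr, ctr[1L, , drop = FALSE])))
  axial <- sum(rowSums(steps) == 1)
  diag_ <- sum(steps[, 1] == 1 & steps[, 2] == 1)
  other <- steps[rowSums(steps) > 2, , drop = FALSE]  # contour jumps
  0.948 * axial + 1.340 * diag_ +
    if (nrow(other)) sum(sqrt(other[, 1]^2 + other[, 2]^2)) else 0
}

#' Measure the morphological shape parameters of a segmented organoid
#'
#' Computes the size and shape descriptors used for organoid quality
#' assessment, in physical units: area (pixel count times pixel area),
#' perimeter (corner-corrected Kulpa length of the closed chain through
#' boundary-pixel centers, so smooth outlines are not overestimated by
#' the pixel staircase), maximal Feret diameter (rotating calipers over the convex
#' hull of boundary-pixel centers), aspect ratio and roundness from the
#' moment-equivalent ellipse, circularity \eqn{4\pi A / P^2} (capped at
#' 1), and solidity (area over convex-hull area, hull taken over
#' boundary-pixel corners so that pixel-count and hull areas are
#' commensurate; capped at 1).
#'
#' @param mask An `organoid_mask` from [segment_organoid()], or a logical/
#'   0-1 matrix together with `pixel_size_um`.
#' @param pixel_size_um Pixel size in µm/px; taken from the mask object
#'   when omitted.
#' @param id Optional organoid identifier for the output row.
#' @return A one-row `data.frame` with columns `organoid_id`, `area_um2`,
#'   `perimeter_um`, `feret_um`, `aspect_ratio`, `circularity`,
#'   `roundness`, `solidity`, and the cyst columns `cysts_count`,
#'   `cysts_area_ratio` set to `NA` (see [detect_cysts()]).
#' @export
measure_shape <- function(mask, pixel_size_um = NULL, id = NULL) {
  p <- mask_pixel_size(mask, pixel_size_um)
  if (is.null(id) && inherits(mask, "organoid_mask")) id <- mask$id
  m <- as_mask_matrix(mask)
  n_px <- sum(m)
  if (n_px < 3L) stop("measurement error: mask has fewer than 3 pixels")

  ctr <- mask_contour(m)
  perim_px <- chain_perimeter(ctr)
  bpx <- boundary_pixels(m)
  feret_px <- feret_diameter(bpx)

  # moment-equivalent ellipse; 1/12 is the variance of a unit pixel square
  idx <- which(m, arr.ind = TRUE)
  x <- idx[, 1]; y <- idx[, 2]
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + disc
  l2 <- max((mu20 + mu02) / 2 - disc, 1e-12)
  major_px <- 4 * sqrt(l1)
  minor_px <- 4 * sqrt(l2)

  # hull over the four corners of each boundary pixel, so hull area is on
  # the same (pixel-counting) footing as the mask area
  corners <- rbind(cbind(bpx[, 1] - 0.5, bpx[, 2] - 0.5),
                   cbind(bpx[, 1] - 0.5, bpx[, 2] + 0.5),
                   cbind(bpx[, 1] + 0.5, bpx[, 2] - 0.5),
                   cbind(bpx[, 1] + 0.5, bpx[, 2] + 0.5))
  hull_area <- polygon_area(corners[chull(corners), , drop = FALSE])

  data.frame(
    organoid_id = if (is.null(id)) NA_character_ else as.character(id),
    area_um2 = n_px * p^2,
    perimeter_um = perim_px * p,
    feret_um = feret_px * p,
    aspect_ratio = major_px / minor_px,
    circularity = min(1, 4 * pi * n_px / perim_px^2),
    roundness = min(1, 4 * n_px / (pi * major_px^2)),
    solidity = min(1, n_px / hull_area),
    cysts_count = NA_integer_,
    cysts_area_ratio = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Detect fluid-filled cysts inside a segmented organoid
#'
#' Cysts appear as translucent (bright) regions inside the dark organoid
#' body in brightfield images. The image is lightly smoothed, an Otsu
#' threshold is computed from interior pixels only, and bright interior
#' components at least `min_cyst_area_um2` large are counted. Their summed
#' area is reported as a proportion of the organoid area.
#'
#' @param image Grayscale matrix, same geometry as the mask.
#' @param mask `organoid_mask` (or logical matrix plus `pixel_size_um`).
#' @param min_cyst_area_um2 Minimum cyst area in µm² (default 2000).
#' @param min_contrast Minimum interior intensity range (8-bit levels)
#'   required before any cyst is called; below it the interior is treated
#'   as homogeneous (default 16).
#' @param pixel_size_um Pixel size, if `mask` is a plain matrix.
#' @return List with `cysts_count` (integer) and `cysts_area_ratio`
#'   (cyst area / organoid area, in \[0, 1)).
#' @export
detect_cysts <- function(image, mask, min_cyst_area_um2 = 2000,
                         min_contrast = 16, pixel_size_um = NULL) {
  if (!is.numeric(min_cyst_area_um2) || min_cyst_area_um2 <= 0)
    stop("`min_cyst_area_um2` must be positive")
  p <- mask_pixel_size(mask, pixel_size_um)
  m <- as_mask_matrix(mask)
  stopifnot(all(dim(image) == dim(m)))
  img <- to_uint8(image)
  img <- EBImage::gblur(EBImage::Image(img / 255), sigma = 2)@.Data * 255
  # drop a border band ~3 sigma wide: smoothing bleeds the bright
  # background across the organoid edge, which would mimic a cyst rim
  core <- EBImage::erode(m * 1, EBImage::makeBrush(13L, "disc")) > 0
  area_px <- sum(m)
  m <- if (any(core)) core else m
  interior <- img[m]
  none <- list(cysts_count = 0L, cysts_area_ratio = 0)
  if (length(interior) == 0L || diff(range(interior)) < min_contrast)
    return(none)
  thr <- EBImage::otsu(EBImage::Image(matrix(interior / 255, ncol = 1L)),
                       range = c(0, 1), levels = 256) * 255
  bright <- m & (img > thr)
  if (!any(bright)) return(none)
  lab <- EBImage::bwlabel(bright)
  sizes <- tabulate(as.integer(lab))
  min_px <- min_cyst_area_um2 / p^2
  keep <- sizes >= min_px
  list(cysts_count = sum(keep),
       cysts_area_ratio = sum(sizes[keep]) / area_px)
}

#' Measure one organoid image end to end
#'
#' Convenience wrapper: segmentation, shape measurement and cyst detection
#' on a single brightfield image.
#'
#' @inheritParams segment_organoid
#' @inheritParams detect_cysts
#' @return A one-row `data.frame` as from [measure_shape()] with the cyst
#'   columns filled in.
#' @export
measure_organoid <- function(image, pixel_size_um, id = NULL,
                             polarity = "dark", offset = 0,
                             min_cyst_area_um2 = 2000) {
  mask <- segment_organoid(image, pixel_size_um, polarity = polarity,
                           offset = offset, id = id)
  rec <- measure_shape(mask)
  cy <- detect_cysts(image, mask, min_cyst_area_um2 = min_cyst_area_um2)
  rec$cysts_count <- cy$cysts_count
  rec$cysts_area_ratio <- cy$cysts_area_ratio
  rec
}

#' Corrected fluorescence intensity within a mask
#'
#' CFI = integrated density − (mask area × mean background intensity),
#' the standard background-corrected integrated intensity; also returned
#' normalized by the mask area.
#'
#' @param image Grayscale intensity matrix.
#' @param mask Logical matrix or `organoid_mask` defining the organoid.
#' @param background_region Logical matrix marking background pixels;
#'   must be disjoint from the mask and non-empty.
#' @return List with `integrated_density`, `area_px`,
#'   `background_mean_intensity`, `cfi` and `cfi_per_area`.
#' @export
corrected_fluorescence_intensity <- function(image, mask,
                                             background_region) {
  m <- as_mask_matrix(mask)
  b <- background_region > 0
  stopifnot(all(dim(image) == dim(m)), all(dim(b) == dim(m)))
  if (!any(b)) stop("measurement error: empty background region")
  if (any(b & m)) stop("background region overlaps the mask")
  int_den <- sum(image[m])
  area_px <- sum(m)
  bg <- mean(image[b])
  cfi <- int_den - area_px * bg
  list(integrated_density = int_den, area_px = area_px,
       background_mean_intensity = bg, cfi = cfi,
       cfi_per_area = cfi / area_px)
}

#' Mean fluorescence intensity within a mask
#'
#' @param image Grayscale intensity matrix.
#' @param mask Logical matrix or `organoid_mask`.
#' @return Mean intensity over foreground pixels.
#' @export
mean_fluorescence_intensity <- function(image, mask) {
  m <- as_mask_matrix(mask)
  stopifnot(all(dim(image) == dim(m)))
  if (!any(m)) stop("measurement error: empty mask")
  mean(image[m])
}

#' Feret diameter of an organoid section mask
#'
#' @param mask `organoid_mask`, or logical matrix plus `pixel_size_um`.
#' @param pixel_size_um Pixel size in µm/px when `mask` is a matrix.
#' @return Section Feret diameter in micrometres.
#' @export
section_feret <- function(mask, pixel_size_um = NULL) {
  p <- mask_pixel_size(mask, pixel_size_um)
  m <- as_mask_matrix(mask)
  if (sum(m) < 3L) stop("measurement error: mask has fewer than 3 pixels")
  feret_diameter(boundary_pixels(m)) * p
}

#' Read a grayscale image from TIFF or PNG
#'
#' @param path Image file path.
#' @return Numeric matrix on \[0, 1\]; multi-channel images are reduced to
#'   their first channel.
#' @export
read_organoid_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- img@.Data
  if (length(d) > 2L) a <- array(a, dim = d)[, , 1]
  as.matrix(a)
}

#' Write a binary mask as an 8-bit image
#'
#' @param mask `organoid_mask` or logical matrix.
#' @param path Output path (`.tif` or `.png`).
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  EBImage::writeImage(EBImage::Image(m * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' Measure a directory of organoid images into a feature table
#'
#' Applies [measure_organoid()] to every TIFF/PNG in a directory; file
#' names (minus extension) become organoid ids.
#'
#' @param dir Directory of images.
#' @param pixel_size_um Pixel size in µm/px shared by all images.
#' @param ... Passed to [measure_organoid()].
#' @return Feature `data.frame`, one row per image.
#' @export
measure_image_dir <- function(dir, pixel_size_um, ...) {
  paths <- list.files(dir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(paths) == 0L) stop("no TIFF/PNG images found in ", dir)
  recs <- lapply(paths, function(pth) {
    measure_organoid(read_organoid_image(pth), pixel_size_um,
                     id = sub("\\.[^.]+$", "", basename(pth)), ...)
  })
  do.call(rbind, recs)
}
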