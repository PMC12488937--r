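# Fixtures and independent oracles shared across the suite.
# Everything here is deliberately naive (O(n^2) scans, hand-rolled
# step-up, enumeration) and independent of the package internals.

# --- raster fixtures -------------------------------------------------------

disc_mask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  x <- matrix(seq_len(n), n, n) - c0
  y <- matrix(seq_len(n), n, n, byrow = TRUE) - c0
  x^2 + y^2 <= r^2
}

# right triangle with legs a (rows) and b (cols)
triangle_mask <- function(a, b, pad = 4L) {
  m <- matrix(FALSE, a + 2L * pad, b + 2L * pad)
  for (i in seq_len(a)) {
    w <- max(1L, ceiling(b * (1 - (i - 1) / a)))
    m[pad + i, pad + seq_len(w)] <- TRUE
  }
  m
}

# random star-convex blob (low-order radial harmonics), optionally rotated
blob_mask <- function(radius = 18, size = 64L, phi = 0, amps = NULL,
                      phases = NULL) {
  if (is.null(amps)) amps <- runif(4, 0, 0.12)
  if (is.null(phases)) phases <- runif(4, 0, 2 * pi)
  c0 <- (size + 1) / 2
  x <- matrix(seq_len(size), size, size) - c0
  y <- matrix(seq_len(size), size, size, byrow = TRUE) - c0
  th <- atan2(y, x) - phi
  r <- radius * (1 + amps[1] * cos(2 * th + phases[1]) +
                   amps[2] * cos(3 * th + phases[2]) +
                   amps[3] * cos(4 * th + phases[3]) +
                   amps[4] * cos(5 * th + phases[4]))
  sqrt(x^2 + y^2) <= pmax(r, 3)
}

# dark disc organoid image with optional bright cyst discs
disc_image <- function(r, cysts = list(), pad = 8L, bg = 200, body = 80,
                       cyst_val = 170) {
  m <- disc_mask(r, pad)
  img <- matrix(bg, nrow(m), ncol(m))
  img[m] <- body
  c0 <- (nrow(m) + 1) / 2
  x <- matrix(seq_len(nrow(m)), nrow(m), ncol(m)) - c0
  y <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE) - c0
  for (cy in cysts)
    img[m & ((x - cy[1])^2 + (y - cy[2])^2 <= cy[3]^2)] <- cyst_val
  img
}

# --- geometry oracles ------------------------------------------------------

# O(n^2) maximum pairwise distance over every foreground pixel center
brute_force_feret <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  max(dist(pts))
}

# --- statistics oracles ----------------------------------------------------

# Benjamini-Hochberg step-up, written out from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# exhaustive Youden scan over all midpoint thresholds of the oriented
# ROC (direction is fixed by the AUC contract), with the same tie-break
# (higher specificity, then smaller threshold)
brute_force_youden <- function(x, y01, direction = NULL) {
  u <- sort(unique(x))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  if (is.null(direction)) {
    rk <- rank(x)
    n1 <- sum(y01 == 1)
    auc_high <- (sum(rk[y01 == 1]) - n1 * (n1 + 1) / 2) /
      (n1 * sum(y01 == 0))
    direction <- if (auc_high >= 0.5) "high_feature=>High" else
      "high_feature=>Low"
  }
  best <- list(j = -Inf)
  for (dir in direction) {
    for (t in thr) {
      hi <- x >= t
      pred <- if (dir == "high_feature=>High") hi else !hi
      se <- sum(pred & y01 == 1) / sum(y01 == 1)
      sp <- sum(!pred & y01 == 0) / sum(y01 == 0)
      j <- se + sp - 1
      better <- j > best$j ||
        (j == best$j && sp > best$sp) ||
        (j == best$j && sp == best$sp && t < best$t)
      if (better) best <- list(j = j, t = t, se = se, sp = sp, dir = dir)
    }
  }
  best
}

# AUC as the fraction of High/Low pairs ranked correctly (ties half)
brute_force_auc <- function(x, y01) {
  xh <- x[y01 == 1]; xl <- x[y01 == 0]
  s <- 0
  for (a in xh) for (b in xl) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(xh) * length(xl))
}

# mean silhouette width of a 2-class labelling in a point cloud
silhouette_mean <- function(X, cl) {
  D <- as.matrix(dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    a <- mean(D[i, cl == cl[i] & seq_len(nrow(X)) != i])
    b <- mean(D[i, cl != cl[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# small fast cohort used where expression content is irrelevant
fast_config <- function(seed = 11, ...) {
  cohort_config(n_genes = 200L, seed = seed, ...)
}
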