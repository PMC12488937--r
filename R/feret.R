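#' Maximal Feret diameter of a point set
#'
#' Computes the maximal caliper (Feret) diameter — the largest distance
#' between any two points of a 2-D point cloud — by rotating calipers over
#' the convex hull, so the cost is linear in hull size after the hull is
#' found. Points are typically boundary-pixel centers of a segmented mask.
#'
#' @param pts Two-column numeric matrix of point coordinates.
#' @return The maximal pairwise distance (same units as `pts`).
#' @examples
#' feret_diameter(cbind(c(0, 3, 0), c(0, 0, 4)))  # 5
#' @export
feret_diameter <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stop("`pts` must be a two-column matrix")
  if (nrow(pts) < 2L) return(0)
  h <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  rotating_calipers_diameter(h)
}

# Maximum distance between vertices of a convex polygon (antipodal pairs).
# `h` holds hull vertices in the (clockwise) order returned by chull().
rotating_calipers_diameter <- function(h) {
  n <- nrow(h)
  if (n == 1L) return(0)
  d2 <- function(i, j) {
    dx <- h[i, 1] - h[j, 1]; dy <- h[i, 2] - h[j, 2]
    dx * dx + dy * dy
  }
  if (n == 2L) return(sqrt(d2(1L, 2L)))
  # twice the triangle area spanned by edge (i,j) and vertex k
  area2 <- function(i, j, k) {
    abs((h[j, 1] - h[i, 1]) * (h[k, 2] - h[i, 2]) -
        (h[j, 2] - h[i, 2]) * (h[k, 1] - h[i, 1]))
  }
  best <- 0
  k <- 2L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    repeat {
      k2 <- if (k == n) 1L else k + 1L
      if (area2(i, j, k2) > area2(i, j, k)) k <- k2 else break
    }
    best <- max(best, d2(i, k), d2(j, k))
  }
  sqrt(best)
}

# shoelace area of a polygon given as an n x 2 vertex matrix
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# perimeter of a closed polygon through the given vertices, in order
polygon_perimeter <- function(p) {
  n <- nrow(p)
  if (n < 2L) return(0)
  j <- c(seq_len(n)[-1L], 1L)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}
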