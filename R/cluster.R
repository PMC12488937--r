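#' Z-score normalization of feature columns
#'
#' Centers each requested column to mean 0 and scales to sample SD 1.
#'
#' @param table `data.frame` or matrix.
#' @param features Columns to normalize (default: all numeric columns of
#'   a matrix, the nine morphological parameters of a feature table).
#' @return Numeric matrix of normalized columns.
#' @export
zscore_normalize <- function(table, features = NULL) {
  if (is.null(features))
    features <- if (is.data.frame(table))
      intersect(qc_feature_names(), names(table)) else colnames(table)
  X <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero variance in column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Within-cluster sum-of-squares profile and elbow choice of k
#'
#' Runs best-of-`n_start` k-means for `k = 1..k_max` and records the
#' total within-cluster sum of squares. The elbow is chosen
#' deterministically as the `k` (restricted to `2..(k_max - 1)`)
#' maximizing the discrete second difference
#' `wss(k-1) - 2 wss(k) + wss(k+1)` — a reproducible surrogate for
#' reading the bend off the WSS plot.
#'
#' @param matrix Numeric matrix (rows = organoids), typically the
#'   z-scored selected features.
#' @param k_max Largest k profiled (default 15).
#' @param n_start Random starts per k (default 20).
#' @param seed RNG seed governing all starts (default 111).
#' @return Object of class `qc_elbow`: list with `k`, `wss`, `chosen_k`.
#' @export
elbow_wss <- function(matrix, k_max = 15L, n_start = 20L, seed = 111L) {
  X <- as.matrix(matrix)
  if (nrow(X) <= k_max) stop("need more rows than k_max")
  set.seed(seed)
  wss <- numeric(k_max)
  wss[1] <- sum(scale(X, center = TRUE, scale = FALSE)^2)
  for (k in 2:k_max)
    wss[k] <- kmeans_best(X, k, n_start)$tot.withinss
  ks <- 2:(k_max - 1L)
  d2 <- wss[ks - 1L] - 2 * wss[ks] + wss[ks + 1L]
  chosen <- ks[which.max(d2)]
  structure(list(k = seq_len(k_max), wss = wss, chosen_k = chosen),
            class = "qc_elbow")
}

#' @export
print.qc_elbow <- function(x, ...) {
  cat("Elbow profile over k = 1..", max(x$k), ": chosen k = ",
      x$chosen_k, "\n", sep = "")
  invisible(x)
}

#' @export
plot.qc_elbow <- function(x, ...) {
  plot(x$k, x$wss, type = "b", xlab = "k",
       ylab = "total within-cluster SS", ...)
  abline(v = x$chosen_k, lty = 2)
  invisible(x)
}

# best-of-n_start k-means under the ambient RNG stream, with retry on the
# rare empty-cluster/quick-transfer failure
kmeans_best <- function(X, k, n_start) {
  for (attempt in 1:5) {
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = k, nstart = n_start,
                              iter.max = 100L)),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) return(km)
  }
  stop("k-means failed to produce ", k, " non-empty clusters")
}

#' K-means clustering of organoids
#'
#' Best-of-`n_start` k-means (squared Euclidean, random initialization)
#' on the given matrix; the seed governs all starts so the partition is
#' reproducible.
#'
#' @inheritParams elbow_wss
#' @param k Number of clusters (default 2).
#' @return List with `cluster` (integer vector), `centers`,
#'   `tot_withinss`, and the underlying `kmeans` fit.
#' @export
kmeans_cluster <- function(matrix, k = 2L, n_start = 20L, seed = 111L) {
  X <- as.matrix(matrix)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(X) <= k) stop("need more rows than clusters")
  set.seed(seed)
  km <- kmeans_best(X, k, n_start)
  list(cluster = km$cluster, centers = km$centers,
       tot_withinss = km$tot.withinss, fit = km)
}

#' Map two clusters to High/Low quality labels
#'
#' The cluster with the higher proportion of expert-High organoids is
#' mapped to High; an exact tie is broken toward the cluster with the
#' smaller mean Feret diameter (small organoids are the high-quality
#' ones).
#'
#' @param cluster Integer vector with two distinct values.
#' @param labels Expert High/Low labels.
#' @param feret Optional Feret diameters, used only to break ties.
#' @return Factor of mapped `"High"`/`"Low"` labels, one per organoid;
#'   the cluster-to-label map is attached as attribute `mapping`.
#' @export
map_clusters_to_labels <- function(cluster, labels, feret = NULL) {
  y <- encode_high_low(labels)
  ids <- sort(unique(cluster))
  if (length(ids) != 2L) stop("expected exactly two clusters")
  prop_high <- vapply(ids, function(cl) mean(y[cluster == cl]), numeric(1))
  if (prop_high[1] == prop_high[2]) {
    if (is.null(feret))
      stop("tied High proportions; supply `feret` to break the tie")
    mf <- vapply(ids, function(cl) mean(feret[cluster == cl]), numeric(1))
    high_cl <- ids[which.min(mf)]
  } else {
    high_cl <- ids[which.max(prop_high)]
  }
  mapping <- setNames(ifelse(ids == high_cl, "High", "Low"),
                      as.character(ids))
  out <- factor(mapping[as.character(cluster)], levels = c("High", "Low"))
  attr(out, "mapping") <- mapping
  out
}

#' Agreement between predicted and expert quality labels
#'
#' 2x2 confusion counts and derived rates with High as the positive
#' class: PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity, specificity
#' and accuracy. An undefined rate (empty denominator) is returned as
#' `NA` with a warning.
#'
#' @param predicted,expert High/Low label vectors of equal length.
#' @return Object of class `qc_agreement`: list of counts and rates.
#' @export
agreement_metrics <- function(predicted, expert) {
  p <- encode_high_low(predicted)
  e <- encode_high_low(expert)
  if (length(p) != length(e)) stop("label vectors differ in length")
  tp <- sum(p == 1 & e == 1); fp <- sum(p == 1 & e == 0)
  tn <- sum(p == 0 & e == 0); fn <- sum(p == 0 & e == 1)
  safe_rate <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (empty denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn, n = length(p),
    ppv = safe_rate(tp, tp + fp, "PPV"),
    npv = safe_rate(tn, tn + fn, "NPV"),
    sensitivity = safe_rate(tp, tp + fn, "sensitivity"),
    specificity = safe_rate(tn, tn + fp, "specificity"),
    accuracy = (tp + tn) / length(p)
  ), class = "qc_agreement")
}

#' @export
print.qc_agreement <- function(x, ...) {
  cat(sprintf("Agreement (High = positive): TP %d  FP %d  TN %d  FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  PPV %.1f%%  NPV %.1f%%  Se %.1f%%  Sp %.1f%%  Acc %.1f%%\n",
              100 * x$ppv, 100 * x$npv, 100 * x$sensitivity,
              100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}
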