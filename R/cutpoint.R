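#' ROC curve of a single morphological feature against the expert rating
#'
#' Candidate thresholds are the midpoints between consecutive sorted
#' unique feature values plus infinite sentinels. The feature direction
#' is chosen automatically so that the oriented AUC is at least 0.5:
#' `"high_feature=>Low"` when large values indicate Low quality (the
#' Feret-diameter case), `"high_feature=>High"` otherwise. High is the
#' positive class throughout.
#'
#' @param feature Numeric vector.
#' @param labels Expert High/Low labels.
#' @param feature_name Optional name stored in the result.
#' @return Object of class `qc_roc`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `direction`, `auc`, `feature`, and the
#'   input data (`x`, `y`).
#' @export
roc_curve <- function(feature, labels, feature_name = NULL) {
  y <- encode_high_low(labels)
  x <- as.numeric(feature)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(y)) < 2L) stop("both classes must be present")

  # AUC for the rule "larger feature => High", ties counted half;
  # equals the normalized Mann-Whitney U statistic
  rk <- rank(x)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc_high <- (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc_high >= 0.5) "high_feature=>High" else
    "high_feature=>Low"
  auc <- max(auc_high, 1 - auc_high)

  u <- sort(unique(x))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  pred_high <- if (direction == "high_feature=>High")
    function(t) x >= t else function(t) x < t
  se <- vapply(thr, function(t) sum(pred_high(t) & y == 1) / n1, numeric(1))
  sp <- vapply(thr, function(t) sum(!pred_high(t) & y == 0) / n0, numeric(1))

  structure(list(thresholds = thr, sensitivity = se, specificity = sp,
                 direction = direction, auc = auc,
                 feature = feature_name %||% deparse(substitute(feature)),
                 x = x, y = y),
            class = "qc_roc")
}

#' @export
print.qc_roc <- function(x, ...) {
  cat("ROC for ", x$feature, ": AUC = ", round(x$auc, 3),
      ", direction ", x$direction, "\n", sep = "")
  invisible(x)
}

#' @export
plot.qc_roc <- function(x, ...) {
  o <- order(1 - x$specificity, x$sensitivity)
  plot(1 - x$specificity[o], x$sensitivity[o], type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = paste("ROC:", x$feature), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal cutpoint of a feature
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over all
#' candidate thresholds of a [roc_curve()]. Ties are broken toward the
#' threshold with the higher specificity, then toward the smaller
#' threshold value.
#'
#' @param roc A `qc_roc` object.
#' @return Object of class `qc_cutpoint`: list with `feature`,
#'   `optimal_threshold`, `youden_j`, `direction`, `sensitivity`,
#'   `specificity`, `auc` and `agreement` (a [agreement_metrics()] of the
#'   thresholded labels against the expert labels the ROC was built on).
#' @export
youden_optimal_cutpoint <- function(roc) {
  stopifnot(inherits(roc, "qc_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  o <- order(-j, -roc$specificity, roc$thresholds)
  best <- o[1]
  pred <- classify_by_threshold(roc$x, roc$thresholds[best], roc$direction)
  agree <- agreement_metrics(pred, ifelse(roc$y == 1, "High", "Low"))
  structure(list(feature = roc$feature,
                 optimal_threshold = roc$thresholds[best],
                 youden_j = j[best],
                 direction = roc$direction,
                 sensitivity = roc$sensitivity[best],
                 specificity = roc$specificity[best],
                 auc = roc$auc,
                 agreement = agree),
            class = "qc_cutpoint")
}

#' @export
print.qc_cutpoint <- function(x, ...) {
  cat(sprintf("Youden cutpoint for %s: threshold %.6g (%s), J = %.3f\n",
              x$feature, x$optimal_threshold, x$direction, x$youden_j))
  print(x$agreement)
  invisible(x)
}

#' Classify organoids by a single-feature threshold
#'
#' For direction `"high_feature=>Low"` (the Feret-diameter convention):
#' values below the threshold are High quality, values at or above it
#' are Low. For `"high_feature=>High"` the rule is mirrored (the
#' threshold itself classifies with the large-value side).
#'
#' @param feature Numeric vector.
#' @param threshold Finite threshold in feature units.
#' @param direction `"high_feature=>Low"` or `"high_feature=>High"`.
#' @param expert Optional expert labels; when given, agreement metrics
#'   are attached.
#' @return Factor of `"High"`/`"Low"` labels; when `expert` is supplied,
#'   a list with `labels` and `agreement`.
#' @export
classify_by_threshold <- function(feature, threshold,
                                  direction = "high_feature=>Low",
                                  expert = NULL) {
  direction <- match.arg(direction,
                         c("high_feature=>Low", "high_feature=>High"))
  hi_side <- as.numeric(feature) >= threshold
  lab <- if (direction == "high_feature=>Low")
    ifelse(hi_side, "Low", "High") else ifelse(hi_side, "High", "Low")
  lab <- factor(lab, levels = c("High", "Low"))
  if (is.null(expert)) return(lab)
  list(labels = lab, agreement = agreement_metrics(lab, expert))
}
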