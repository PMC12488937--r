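#' Fit the organoid quality classifier from a feature table
#'
#' The central modelling step: from a per-organoid feature table with an
#' expert High/Low rating, (i) screen the nine morphological parameters
#' by point-biserial correlation under FDR control, (ii) confirm the
#' selected parameters by k-means clustering (elbow-chosen k, agreement
#' with the expert via PPV/NPV), and (iii) derive the Youden-optimal
#' threshold for each selected parameter, promoting the configured
#' feature (by default the maximal Feret diameter) to the final
#' single-parameter classifier.
#'
#' @param data `data.frame` with the nine feature columns (see
#'   [qc_feature_names()]) and an expert label column.
#' @param label_col Name of the High/Low expert column
#'   (default `"expert_label"`).
#' @param features Feature columns to consider.
#' @param p_cut,r_cut Screening cutoffs (defaults `1e-5` and `0.5`).
#' @param k_max,n_start,seed K-means settings: elbow profile over
#'   `1..k_max`, best of `n_start` random starts, RNG `seed`
#'   (defaults 15, 20, 111).
#' @param cutpoint_feature Feature used for the final threshold
#'   classifier (default `"feret_um"`).
#' @return Object of class `organoid_qc`, a list with components
#'   `screen` ([screen_features()] result), `elbow`, `cluster`
#'   (assignment, mapped labels, agreement), `cutpoints` (one
#'   [youden_optimal_cutpoint()] per selected feature), `classifier`
#'   (the cutpoint of `cutpoint_feature`, with threshold agreement), and
#'   `call`/`settings`. Supports `print()`, `summary()`, `coef()`,
#'   `predict()` and `plot()`.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' fit <- organoid_qc(coh$truth)
#' coef(fit)
#' predict(fit, data.frame(feret_um = c(2100, 4200)))
#' @export
organoid_qc <- function(data, label_col = "expert_label",
                        features = qc_feature_names(),
                        p_cut = 1e-5, r_cut = 0.5,
                        k_max = 15L, n_start = 20L, seed = 111L,
                        cutpoint_feature = "feret_um") {
  stopifnot(is.data.frame(data))
  if (!cutpoint_feature %in% features)
    stop("`cutpoint_feature` must be one of the screened features")
  labels <- data[[label_col]]
  if (is.null(labels)) stop("label column '", label_col, "' not found")

  scr <- screen_features(data, features = features, label_col = label_col,
                         p_cut = p_cut, r_cut = r_cut)
  sel <- scr$feature[scr$selected]
  # clustering needs >= 2 dimensions; fall back to the top correlates
  clus_features <- if (length(sel) >= 2L) sel else
    scr$feature[seq_len(min(5L, nrow(scr)))]

  Z <- zscore_normalize(data, clus_features)
  elbow <- elbow_wss(Z, k_max = k_max, n_start = n_start, seed = seed)
  km <- kmeans_cluster(Z, k = 2L, n_start = n_start, seed = seed)
  mapped <- map_clusters_to_labels(km$cluster, labels,
                                   feret = data[["feret_um"]])
  cl_agree <- agreement_metrics(mapped, labels)

  cutpoints <- lapply(sel, function(f)
    youden_optimal_cutpoint(roc_curve(data[[f]], labels,
                                      feature_name = f)))
  names(cutpoints) <- sel
  classifier <- if (cutpoint_feature %in% sel)
    cutpoints[[cutpoint_feature]] else
    youden_optimal_cutpoint(roc_curve(data[[cutpoint_feature]], labels,
                                      feature_name = cutpoint_feature))

  structure(list(
    screen = scr,
    elbow = elbow,
    cluster = list(assignment = km$cluster, mapped = mapped,
                   agreement = cl_agree, features = clus_features,
                   tot_withinss = km$tot_withinss),
    cutpoints = cutpoints,
    classifier = classifier,
    settings = list(label_col = label_col, features = features,
                    p_cut = p_cut, r_cut = r_cut, k_max = k_max,
                    n_start = n_start, seed = seed,
                    cutpoint_feature = cutpoint_feature),
    n = nrow(data),
    call = match.call()
  ), class = "organoid_qc")
}

#' @export
print.organoid_qc <- function(x, ...) {
  cat("Organoid quality classifier (n =", x$n, "organoids)\n")
  cat("  selected features:",
      if (any(x$screen$selected))
        paste(x$screen$feature[x$screen$selected], collapse = ", ")
      else "none", "\n")
  cat("  elbow k =", x$elbow$chosen_k,
      "| k-means (k = 2) PPV", sprintf("%.1f%%,", 100 * x$cluster$agreement$ppv),
      "NPV", sprintf("%.1f%%\n", 100 * x$cluster$agreement$npv))
  cat(sprintf("  classifier: %s %s %.6g (J = %.3f), PPV %.1f%%, NPV %.1f%%\n",
              x$classifier$feature,
              if (x$classifier$direction == "high_feature=>Low") "<" else ">=",
              x$classifier$optimal_threshold, x$classifier$youden_j,
              100 * x$classifier$agreement$ppv,
              100 * x$classifier$agreement$npv))
  invisible(x)
}

#' @export
summary.organoid_qc <- function(object, ...) {
  print(object)
  cat("\nScreen:\n"); print(object$screen)
  cat("\nPer-feature Youden cutpoints:\n")
  for (cp in object$cutpoints)
    cat(sprintf("  %-18s J = %.3f at %.6g (%s)\n", cp$feature,
                cp$youden_j, cp$optimal_threshold, cp$direction))
  invisible(object)
}

#' @export
coef.organoid_qc <- function(object, ...) {
  c(threshold = object$classifier$optimal_threshold,
    youden_j = object$classifier$youden_j)
}

#' Classify new organoids with a fitted quality classifier
#'
#' Applies the fitted single-parameter threshold to new measurements.
#'
#' @param object An `organoid_qc` fit.
#' @param newdata `data.frame` containing the classifier feature column,
#'   or a bare numeric vector of feature values.
#' @param ... Unused.
#' @return Factor of predicted `"High"`/`"Low"` quality labels.
#' @export
predict.organoid_qc <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    f <- object$classifier$feature
    if (is.null(newdata[[f]]))
      stop("`newdata` lacks the classifier feature '", f, "'")
    newdata[[f]]
  } else as.numeric(newdata)
  classify_by_threshold(x, object$classifier$optimal_threshold,
                        object$classifier$direction)
}

#' Diagnostic plots of a fitted quality classifier
#'
#' Three panels: the feature screen (|r| bars with the selection cutoff),
#' the elbow profile, and the ROC curve of the final classifier with the
#' chosen threshold marked.
#'
#' @param x An `organoid_qc` fit.
#' @param ... Unused.
#' @export
plot.organoid_qc <- function(x, ...) {
  op <- par(mfrow = c(1, 3))
  on.exit(par(op))
  bar <- abs(x$screen$r_pb)
  barplot(bar, names.arg = x$screen$feature, las = 2,
          ylab = "|point-biserial r|", main = "Feature screen",
          col = ifelse(x$screen$selected, "grey30", "grey80"))
  abline(h = attr(x$screen, "r_cut"), lty = 2)
  plot(x$elbow, main = "Elbow")
  cp <- x$classifier
  plot(1 - cp$agreement$specificity, cp$agreement$sensitivity,
       xlim = c(0, 1), ylim = c(0, 1), pch = 19,
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("%s @ %.5g", cp$feature, cp$optimal_threshold))
  abline(0, 1, lty = 3)
  invisible(x)
}
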