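#' Point-biserial correlation between a feature and a binary quality label
#'
#' Pearson correlation of the feature with the 0/1-encoded label
#' (High = 1, Low = 0); the two-sided p-value comes from the exact t
#' reference distribution, `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param feature Numeric vector.
#' @param label Vector codable as High/Low: a factor/character with
#'   levels `"High"`/`"Low"`, a logical, or 0/1 numeric (1 = High).
#' @return List with `r_pb`, `p_raw`, and `n`.
#' @export
point_biserial <- function(feature, label) {
  y <- encode_high_low(label)
  if (length(feature) != length(y)) stop("lengths differ")
  keep <- is.finite(feature) & !is.na(y)
  feature <- feature[keep]; y <- y[keep]
  n <- length(y)
  if (n < 4L) stop("need at least 4 observations")
  if (length(unique(y)) < 2L)
    stop("undefined correlation: labels contain a single class")
  if (var(feature) == 0)
    stop("undefined correlation: feature has zero variance")
  r <- cor(feature, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(r_pb = r, p_raw = p, n = n)
}

# High -> 1, Low -> 0
encode_high_low <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(label))
  }
  label <- as.character(label)
  if (!all(label %in% c("High", "Low")))
    stop("labels must be 'High'/'Low' (or logical / 0-1)")
  as.integer(label == "High")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p_raw Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (monotone step-up, capped at 1).
#' @export
fdr_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0) || any(p_raw > 1))
    stop("domain error: p-values must lie in [0, 1]")
  p.adjust(p_raw, method = "BH")
}

#' Screen morphological features against the expert quality rating
#'
#' Point-biserial correlation of each feature with the binary expert
#' label, BH-FDR adjustment across the screened family, and selection of
#' features with `p_adj < p_cut` and `|r_pb| > r_cut`. Default cutoffs
#' are the stringent `p_cut = 1e-5`, `r_cut = 0.5`.
#'
#' @param table `data.frame` with the feature columns and a label column.
#' @param features Feature columns to screen (default the nine
#'   morphological parameters, see [qc_feature_names()]).
#' @param label_col Name of the High/Low label column
#'   (default `"expert_label"`).
#' @param p_cut FDR-adjusted p-value cutoff.
#' @param r_cut Absolute point-biserial correlation cutoff.
#' @return Object of class `qc_screen`: `data.frame` with one row per
#'   feature (`feature`, `r_pb`, `p_raw`, `p_adj`, `selected`), ordered
#'   by `|r_pb|` descending.
#' @export
screen_features <- function(table, features = qc_feature_names(),
                            label_col = "expert_label",
                            p_cut = 1e-5, r_cut = 0.5) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c(features, label_col), names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  res <- lapply(features, function(f) {
    pb <- point_biserial(table[[f]], table[[label_col]])
    data.frame(feature = f, r_pb = pb$r_pb, p_raw = pb$p_raw,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- fdr_adjust(res$p_raw)
  res$selected <- res$p_adj < p_cut & abs(res$r_pb) > r_cut
  res <- res[order(-abs(res$r_pb)), ]
  rownames(res) <- NULL
  attr(res, "p_cut") <- p_cut
  attr(res, "r_cut") <- r_cut
  class(res) <- c("qc_screen", "data.frame")
  res
}

#' @export
print.qc_screen <- function(x, ...) {
  cat("Feature screen vs expert rating (p_cut = ",
      format(attr(x, "p_cut")), ", |r| > ", format(attr(x, "r_cut")),
      "):\n", sep = "")
  df <- as.data.frame(x)
  df$r_pb <- round(df$r_pb, 3)
  df$p_raw <- signif(df$p_raw, 3)
  df$p_adj <- signif(df$p_adj, 3)
  print(df, row.names = FALSE)
  cat(sum(x$selected), "of", nrow(x), "features selected\n")
  invisible(x)
}

#' Two-dimensional PCA embedding of the feature table
#'
#' Z-scores the requested features and projects onto the first two
#' principal components; constant features are dropped with a warning.
#' Provided for visualization of the cohort structure.
#'
#' @param table Feature `data.frame`.
#' @param features Feature columns to embed.
#' @return List with `scores` (n x 2 matrix, columns `PC1`, `PC2`),
#'   `var_explained` (full spectrum, fractions), and the `prcomp` fit.
#' @export
pca_embed <- function(table, features = qc_feature_names()) {
  stopifnot(is.data.frame(table))
  X <- as.matrix(table[, features, drop = FALSE])
  keep <- apply(X, 2, function(v) var(v) > 0)
  if (!all(keep)) {
    warning("dropping constant features: ",
            paste(features[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need at least 2 non-constant features")
  fit <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, 1:2, drop = FALSE], var_explained = ve, fit = fit)
}
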