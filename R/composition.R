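#' Estimate cell-type fractions from bulk expression
#'
#' Simplified reference-based deconvolution: each sample is library-size
#' normalized (counts per million, no log), regressed on the signature
#' columns by non-negative least squares (Lawson-Hanson, via
#' [pracma::lsqnonneg()]), and the coefficients are renormalized to sum
#' to one. Genes on a user-supplied exclusion list (mitochondrial,
#' ribosomal, sex-chromosome, MALAT1, ...) are removed before fitting;
#' at least 50 genes shared between bulk and signature must remain.
#' Estimates are deterministic and invariant to per-sample scaling.
#'
#' @param bulk Non-negative genes x samples matrix with gene-id rownames.
#' @param signature Non-negative genes x cell-types matrix with gene-id
#'   rownames; one column should be named `"mesenchymal"` for the
#'   mesenchymal summaries.
#' @param exclusion_list Optional character vector of gene ids to drop.
#' @return Object of class `qc_composition`: list with `fractions`
#'   (samples x cell types, rows on the unit simplex),
#'   `mesenchymal_fraction` (named vector, `NA`-free when the signature
#'   has a mesenchymal column) and `n_genes_used`.
#' @export
estimate_fractions <- function(bulk, signature, exclusion_list = NULL) {
  bulk <- as.matrix(bulk); signature <- as.matrix(signature)
  if (is.null(rownames(bulk)) || is.null(rownames(signature)))
    stop("bulk and signature need gene-id rownames")
  if (any(bulk < 0) || any(signature < 0))
    stop("expression and signature must be non-negative")
  if (any(colSums(signature) == 0)) stop("signature has an all-zero column")
  genes <- setdiff(intersect(rownames(bulk), rownames(signature)),
                   exclusion_list)
  if (length(genes) < 50L)
    stop("fewer than 50 shared genes after the exclusion filter")
  B <- bulk[genes, , drop = FALSE]
  S <- signature[genes, , drop = FALSE]
  k <- ncol(S)
  fr <- matrix(NA_real_, ncol(B), k,
               dimnames = list(colnames(B), colnames(S)))
  for (i in seq_len(ncol(B))) {
    y <- B[, i]
    tot <- sum(y)
    if (tot == 0) stop("sample ", colnames(B)[i] %||% i, " is all zero")
    y <- y / tot * 1e6                     # CPM
    beta <- pracma::lsqnonneg(S, y)$x
    if (sum(beta) == 0)
      stop("degenerate fit for sample ", colnames(B)[i] %||% i)
    fr[i, ] <- beta / sum(beta)
  }
  mc <- if ("mesenchymal" %in% colnames(fr))
    setNames(fr[, "mesenchymal"], rownames(fr)) else
    setNames(rep(NA_real_, nrow(fr)), rownames(fr))
  structure(list(fractions = fr, mesenchymal_fraction = mc,
                 n_genes_used = length(genes)),
            class = "qc_composition")
}

#' @export
print.qc_composition <- function(x, ...) {
  cat("Cell-type composition estimates for", nrow(x$fractions),
      "samples (", ncol(x$fractions), "types,", x$n_genes_used,
      "genes )\n")
  if (!all(is.na(x$mesenchymal_fraction)))
    cat(sprintf("  mesenchymal fraction: median %.3f, range %.3f-%.3f\n",
                median(x$mesenchymal_fraction),
                min(x$mesenchymal_fraction),
                max(x$mesenchymal_fraction)))
  invisible(x)
}

#' Coefficient of variation, in percent
#'
#' CV = SD / mean x 100, with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector.
#' @return CV in percent; `NA` with a warning when the mean is zero.
#' @export
cv_percent <- function(x) {
  m <- mean(x)
  if (m == 0) {
    warning("CV undefined for zero mean; reported as NA")
    return(NA_real_)
  }
  sd(x) / m * 100
}

#' Per-line dispersion summary of the mesenchymal fraction
#'
#' Computes the CV (SD/mean x 100) of the mesenchymal fraction within
#' every line, the median and range of these per-line CVs, and the CV of
#' the per-line mean fractions across lines (between-line variability).
#'
#' @param mc_fraction Numeric vector of per-organoid mesenchymal
#'   fractions.
#' @param line_id Line identifier per organoid (>= 2 organoids per line).
#' @return List with `per_line_cv` (named vector, %), `median_cv`,
#'   `cv_range` (length 2), and `cv_of_line_means` (all %).
#' @export
cv_summary <- function(mc_fraction, line_id) {
  stopifnot(length(mc_fraction) == length(line_id))
  sizes <- table(line_id)
  if (any(sizes < 2L))
    stop("every line needs at least 2 samples for a CV")
  per_line <- c(tapply(mc_fraction, line_id, cv_percent))
  means <- tapply(mc_fraction, line_id, mean)
  list(per_line_cv = per_line,
       median_cv = median(per_line, na.rm = TRUE),
       cv_range = range(per_line, na.rm = TRUE),
       cv_of_line_means = cv_percent(as.numeric(means)))
}

#' Two-group comparison of composition fractions
#'
#' Two-sided Wilcoxon rank-sum test of a fraction between two groups
#' (e.g. expert High vs Low, k-means clusters, or Feret-threshold
#' groups). The exact null distribution is used when both groups have at
#' most 25 observations and no ties are present; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param values Numeric vector (e.g. mesenchymal fractions).
#' @param group Two-level grouping vector.
#' @return List with `p_value`, `group_medians` (named), `higher_group`
#'   and `exact` (logical: exact null used).
#' @export
group_difference_test <- function(values, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("grouping must have exactly two levels")
  v1 <- values[g == levels(g)[1]]
  v2 <- values[g == levels(g)[2]]
  if (!length(v1) || !length(v2)) stop("both groups must be non-empty")
  exact <- max(length(v1), length(v2)) <= 25L && !any(duplicated(values))
  ht <- suppressWarnings(
    wilcox.test(v1, v2, alternative = "two.sided", exact = exact,
                correct = TRUE))
  med <- c(median(v1), median(v2))
  names(med) <- levels(g)
  list(p_value = ht$p.value, group_medians = med,
       higher_group = levels(g)[which.max(med)], exact = exact)
}

#' Rank (or linear) correlation with t-based p-value
#'
#' Spearman's rho on average ranks (the default; matches the reported
#' composition-size associations) or Pearson's r, with the two-sided
#' p-value from the t transform `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `estimate`, `p_value`, `method`, `n`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: constant vector")
  r <- if (method == "spearman") cor(rank(x), rank(y)) else cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(estimate = r, p_value = p, method = method, n = n)
}

#' Cohort-level composition statistics
#'
#' Bundles the statistics linking mesenchymal abundance to morphology and
#' quality: per-line CV summary, Wilcoxon comparisons of the mesenchymal
#' fraction across each supplied grouping, and the correlation (Spearman,
#' plus Pearson for reference) between mesenchymal fraction and Feret
#' diameter.
#'
#' @param mc_fraction Per-organoid mesenchymal fractions.
#' @param line_id Line ids.
#' @param feret_um Feret diameters (µm).
#' @param groupings Named list of two-level grouping vectors (e.g.
#'   `list(expert = ..., cluster = ..., feret = ...)`).
#' @return Object of class `qc_composition_stats`: list with `cv`
#'   ([cv_summary()]), `group_tests` (one [group_difference_test()] per
#'   grouping), `spearman_mc_feret` and `pearson_mc_feret`.
#' @export
composition_stats <- function(mc_fraction, line_id, feret_um,
                              groupings = list()) {
  structure(list(
    cv = cv_summary(mc_fraction, line_id),
    group_tests = lapply(groupings, function(g)
      group_difference_test(mc_fraction, g)),
    spearman_mc_feret = rank_correlation(mc_fraction, feret_um,
                                         "spearman"),
    pearson_mc_feret = rank_correlation(mc_fraction, feret_um, "pearson")
  ), class = "qc_composition_stats")
}

#' @export
print.qc_composition_stats <- function(x, ...) {
  cat(sprintf("Mesenchymal-fraction cohort statistics\n"))
  cat(sprintf("  per-line CV: median %.2f%% (range %.2f-%.2f%%); CV of line means %.2f%%\n",
              x$cv$median_cv, x$cv$cv_range[1], x$cv$cv_range[2],
              x$cv$cv_of_line_means))
  for (nm in names(x$group_tests))
    cat(sprintf("  MC by %s: higher in %s, Wilcoxon p = %.3g\n", nm,
                x$group_tests[[nm]]$higher_group,
                x$group_tests[[nm]]$p_value))
  cat(sprintf("  MC ~ Feret: Spearman rho %.3f (p = %.3g); Pearson r %.3f\n",
              x$spearman_mc_feret$estimate, x$spearman_mc_feret$p_value,
              x$pearson_mc_feret$estimate))
  invisible(x)
}

#' Read an expression or signature table from CSV/TSV
#'
#' Expects genes as rows with the gene id in the first column and
#' samples (or cell types) as the remaining columns.
#'
#' @param path File path; the separator is inferred from the extension
#'   (`.tsv` -> tab, otherwise comma).
#' @return Numeric matrix with gene-id rownames.
#' @export
read_expression_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
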