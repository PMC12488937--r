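#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Comma-separated values become vectors; numeric-looking
#' values are converted to numbers.
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num else parts
  }
  out
}

# serialize a flat list (scalars and atomic vectors) as key = value text
write_flat_config <- function(config, path) {
  keys <- names(config)
  fmt <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.numeric(v)) v <- format(v, digits = 15, scientific = FALSE)
    paste0(k, " = ", paste(v, collapse = ", "))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

#' Read a per-organoid feature table
#'
#' CSV with one row per organoid; must contain the nine feature columns
#' and the expert label column.
#'
#' @param path CSV path.
#' @param label_col Expected label column (default `"expert_label"`).
#' @return `data.frame`.
#' @export
read_feature_table <- function(path, label_col = "expert_label") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(qc_feature_names(), label_col), names(df))
  if (length(missing_cols))
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Assemble a pipeline configuration
#'
#' @param features Feature table: a `data.frame`, a CSV path, or `NULL`
#'   when `images_dir` is given.
#' @param images_dir Directory of brightfield images to measure (used
#'   when `features` is `NULL`).
#' @param pixel_size_um Pixel size for image measurement.
#' @param label_col Expert label column name.
#' @param labels Optional label vector for image-based runs (named by
#'   organoid id or in file order).
#' @param expression,signature Optional genes x samples / genes x types
#'   matrices (or CSV paths) enabling the composition stage.
#' @param exclusion_list Optional gene ids excluded from deconvolution.
#' @param line_col Line-id column (default `"line_id"`).
#' @param p_cut,r_cut,k_max,n_start,seed,cutpoint_feature Analysis
#'   settings, defaulting to the study settings (1e-5, 0.5, 15, 20, 111,
#'   `"feret_um"`).
#' @return Named list of class `qc_pipeline_config`.
#' @export
pipeline_config <- function(features = NULL, images_dir = NULL,
                            pixel_size_um = NULL,
                            label_col = "expert_label", labels = NULL,
                            expression = NULL, signature = NULL,
                            exclusion_list = NULL, line_col = "line_id",
                            p_cut = 1e-5, r_cut = 0.5, k_max = 15L,
                            n_start = 20L, seed = 111L,
                            cutpoint_feature = "feret_um") {
  if (is.null(features) && is.null(images_dir))
    stop("either `features` or `images_dir` is required")
  structure(list(features = features, images_dir = images_dir,
                 pixel_size_um = pixel_size_um, label_col = label_col,
                 labels = labels, expression = expression,
                 signature = signature, exclusion_list = exclusion_list,
                 line_col = line_col, p_cut = p_cut, r_cut = r_cut,
                 k_max = k_max, n_start = n_start, seed = seed,
                 cutpoint_feature = cutpoint_feature),
            class = "qc_pipeline_config")
}

#' Run the full quality-determination pipeline
#'
#' Orchestrates measure (optional) -> screen -> cluster -> cutpoint ->
#' composition (optional) with one configuration, collecting every stage
#' result and a reproducibility payload into a quality-control report.
#'
#' @param config A [pipeline_config()] (or plain list with the same
#'   fields).
#' @return Object of class `qc_report`: list with `features` (the table
#'   analysed), `fit` (the [organoid_qc()] object), `composition`
#'   (fractions + [composition_stats()], or `NULL`), `payload` (flat
#'   list of every headline number, as serialized to JSON) and
#'   `provenance`.
#' @export
run_quality_pipeline <- function(config) {
  cfg <- config
  feats <- cfg$features
  if (is.character(feats) && length(feats) == 1L)
    feats <- read_feature_table(feats, cfg$label_col)
  if (is.null(feats)) {
    if (is.null(cfg$pixel_size_um))
      stop("stage 'measure': pixel_size_um is required for image input")
    feats <- measure_image_dir(cfg$images_dir, cfg$pixel_size_um)
    if (is.null(cfg$labels))
      stop("stage 'measure': expert labels are required for image input")
    feats[[cfg$label_col]] <-
      if (!is.null(names(cfg$labels)))
        cfg$labels[feats$organoid_id] else cfg$labels
  }

  fit <- organoid_qc(feats, label_col = cfg$label_col,
                     p_cut = cfg$p_cut, r_cut = cfg$r_cut,
                     k_max = cfg$k_max, n_start = cfg$n_start,
                     seed = cfg$seed,
                     cutpoint_feature = cfg$cutpoint_feature)

  composition <- NULL
  if (!is.null(cfg$expression) && !is.null(cfg$signature)) {
    expr <- cfg$expression
    sig <- cfg$signature
    if (is.character(expr)) expr <- read_expression_table(expr)
    if (is.character(sig)) sig <- read_expression_table(sig)
    est <- estimate_fractions(expr, sig,
                              exclusion_list = cfg$exclusion_list)
    thr_labels <- classify_by_threshold(
      feats[[cfg$cutpoint_feature]], fit$classifier$optimal_threshold,
      fit$classifier$direction)
    groupings <- list(expert = feats[[cfg$label_col]],
                      cluster = as.character(fit$cluster$mapped),
                      feret = as.character(thr_labels))
    line <- feats[[cfg$line_col]]
    stats <- composition_stats(est$mesenchymal_fraction, line,
                               feats$feret_um, groupings)
    composition <- list(estimate = est, stats = stats)
  }

  payload <- report_payload(fit, composition)
  provenance <- list(package = "organoidqc",
                     version = as.character(packageVersion("organoidqc")),
                     seed = cfg$seed,
                     n_organoids = nrow(feats),
                     settings = fit$settings)
  structure(list(features = feats, fit = fit, composition = composition,
                 payload = payload, provenance = provenance,
                 config = cfg),
            class = "qc_report")
}

# flat, JSON-serializable summary of every headline number of a run
report_payload <- function(fit, composition = NULL) {
  cp <- fit$classifier
  payload <- list(
    n_organoids = fit$n,
    selected_features = fit$screen$feature[fit$screen$selected],
    n_selected = sum(fit$screen$selected),
    screen = lapply(seq_len(nrow(fit$screen)), function(i)
      list(feature = fit$screen$feature[i],
           r_pb = fit$screen$r_pb[i],
           p_raw = fit$screen$p_raw[i],
           p_adj = fit$screen$p_adj[i],
           selected = fit$screen$selected[i])),
    elbow_k = fit$elbow$chosen_k,
    kmeans = list(ppv = fit$cluster$agreement$ppv,
                  npv = fit$cluster$agreement$npv,
                  sensitivity = fit$cluster$agreement$sensitivity,
                  specificity = fit$cluster$agreement$specificity),
    cutpoints = lapply(fit$cutpoints, function(x)
      list(feature = x$feature, threshold = x$optimal_threshold,
           youden_j = x$youden_j, direction = x$direction)),
    classifier = list(feature = cp$feature,
                      threshold = cp$optimal_threshold,
                      youden_j = cp$youden_j, direction = cp$direction,
                      auc = cp$auc,
                      ppv = cp$agreement$ppv, npv = cp$agreement$npv,
                      TP = cp$agreement$TP, FP = cp$agreement$FP,
                      TN = cp$agreement$TN, FN = cp$agreement$FN)
  )
  if (!is.null(composition)) {
    st <- composition$stats
    payload$composition <- list(
      median_line_cv = st$cv$median_cv,
      cv_range = st$cv$cv_range,
      cv_of_line_means = st$cv$cv_of_line_means,
      spearman_mc_feret = st$spearman_mc_feret$estimate,
      spearman_p = st$spearman_mc_feret$p_value,
      pearson_mc_feret = st$pearson_mc_feret$estimate,
      group_p = lapply(st$group_tests, function(g) g$p_value))
  }
  payload
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Organoid quality-control report\n")
  print(x$fit)
  if (!is.null(x$composition)) print(x$composition$stats)
  invisible(x)
}

#' Write a quality-control report bundle
#'
#' Writes `report.json` (the payload), `features.csv`, `screen.csv`,
#' `clusters.csv`, `cutpoint.json`, and — when the composition stage ran
#' — `fractions.csv` and `stats.json`, plus a `run.log` of stages and
#' settings.
#'
#' @param report A `qc_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wj <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    p
  }
  paths["report"] <- wj(report$payload, "report.json")
  p <- file.path(out_dir, "features.csv")
  write.csv(report$features, p, row.names = FALSE)
  paths["features"] <- p
  p <- file.path(out_dir, "screen.csv")
  write.csv(as.data.frame(report$fit$screen), p, row.names = FALSE)
  paths["screen"] <- p
  p <- file.path(out_dir, "clusters.csv")
  write.csv(data.frame(organoid_id = report$features$organoid_id,
                       cluster = report$fit$cluster$assignment,
                       mapped_label =
                         as.character(report$fit$cluster$mapped)),
            p, row.names = FALSE)
  paths["clusters"] <- p
  paths["cutpoint"] <- wj(report$payload$classifier, "cutpoint.json")
  if (!is.null(report$composition)) {
    p <- file.path(out_dir, "fractions.csv")
    fr <- report$composition$estimate$fractions
    write.csv(data.frame(organoid_id = rownames(fr), fr,
                         check.names = FALSE), p, row.names = FALSE)
    paths["fractions"] <- p
    paths["stats"] <- wj(report$payload$composition, "stats.json")
  }
  log_lines <- c(
    paste("organoidqc", report$provenance$version),
    paste("seed:", report$provenance$seed),
    paste("organoids:", report$provenance$n_organoids),
    paste("settings:", paste(names(report$fit$settings),
                             vapply(report$fit$settings, function(v)
                               paste(format(v), collapse = ","),
                               character(1)),
                             sep = "=", collapse = " ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  paths["log"] <- file.path(out_dir, "run.log")
  invisible(paths)
}

#' Read back a written report payload
#'
#' Inverse of the `report.json` serialization in [write_report()].
#'
#' @param path Path to `report.json` (or a report directory).
#' @return The payload list.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
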