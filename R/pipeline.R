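## Cohort orchestration: manifests, scan QC, and the end-to-end pipeline
## from timeseries to structure-function components and eigenmode metrics.

#' Validate a cohort manifest
#'
#' A manifest is a data frame with one row per subject: `subject_id`
#' (unique), `timeseries_path` (existing file), covariates and
#' `mean_fd`, plus an optional `diagnosis` label.
#'
#' @param manifest Data frame.
#' @param check_files Verify that every referenced file exists.
#' @return The validated manifest (invisibly classed
#'   `cohort_manifest`).
#' @export
cohort_manifest <- function(manifest, check_files = TRUE) {
  manifest <- as.data.frame(manifest)
  if (!"subject_id" %in% names(manifest)) stop("manifest needs subject_id")
  if (anyDuplicated(manifest$subject_id)) stop("duplicate subject IDs")
  if (check_files && "timeseries_path" %in% names(manifest)) {
    missing <- !file.exists(manifest$timeseries_path)
    if (any(missing))
      stop("missing timeseries file(s): ",
           paste(manifest$subject_id[missing], collapse = ", "))
  }
  class(manifest) <- c("cohort_manifest", "data.frame")
  invisible(manifest)
}

#' Head-motion quality control
#'
#' Flags scans whose mean framewise displacement exceeds the threshold
#' (default 0.55 mm).
#'
#' @param manifest Data frame with `subject_id` and `mean_fd` columns
#'   (or a numeric FD vector).
#' @param threshold_mm Exclusion threshold in mm.
#' @return Data frame of class `qc_report`: `subject_id`, `mean_fd`,
#'   `fd_pass`, `excluded`, `reason`.
#' @export
qc_fd_filter <- function(manifest, threshold_mm = 0.55) {
  if (is.numeric(manifest))
    manifest <- data.frame(subject_id = seq_along(manifest),
                           mean_fd = manifest)
  if (!"mean_fd" %in% names(manifest)) {
    stop("mean framewise displacement missing for scans: ",
         paste(manifest$subject_id, collapse = ", "))
  }
  if (anyNA(manifest$mean_fd))
    stop("mean framewise displacement missing for scans: ",
         paste(manifest$subject_id[is.na(manifest$mean_fd)], collapse = ", "))
  pass <- manifest$mean_fd <= threshold_mm
  out <- data.frame(subject_id = manifest$subject_id,
                    mean_fd = manifest$mean_fd,
                    fd_pass = pass,
                    excluded = !pass,
                    reason = ifelse(pass, "",
                                    sprintf("mean FD > %.2f mm", threshold_mm)),
                    stringsAsFactors = FALSE)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' PCA-based FC outlier detection
#'
#' Stacks flattened FC vectors, runs PCA, and flags scans whose score
#' on the first component lies more than one standard deviation above
#' the mean. The component is oriented so that its score distribution
#' has positive skew (outliers load positive), making the flag
#' reproducible and independent of row order.
#'
#' @param fc_edges Scans x edges matrix of flattened FC values.
#' @return Data frame: `pc1_score`, `outlier`; attribute
#'   `threshold`.
#' @export
qc_fc_pca_outliers <- function(fc_edges) {
  x <- as.matrix(fc_edges)
  if (nrow(x) < 3) stop("need at least 3 scans")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  sc <- pr$x[, 1]
  skew <- mean((sc - mean(sc))^3)
  if (skew < 0) sc <- -sc
  thr <- mean(sc) + stats::sd(sc)
  out <- data.frame(pc1_score = sc, outlier = sc > thr)
  attr(out, "threshold") <- thr
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: scan QC (FD filter and FC-PCA outliers) ->
#' gradient basis from the designated normative pool (the severity-0
#' subjects) -> projection and per-subject FC -> PLSR structure-function
#' components and atrophy PCA -> cross-validated ridge function scores
#' -> per-subject oscillator fits and eigenmode metrics -> metric/moment
#' correlation. Every stage's key outputs are written as plain-text
#' files in `out_dir` together with a summary JSON carrying the seed
#' and a hash of the configuration; reruns with the same seed are
#' identical.
#'
#' @param config A `synth_config` describing the cohort (regenerated
#'   deterministically from its seed).
#' @param out_dir Output directory; created if missing. `NULL` skips
#'   writing.
#' @param fd_threshold Head-motion exclusion threshold (mm).
#' @param n_components PLSR/PCA components (default 3).
#' @param alpha,n_trials Ridge penalty and number of CV trials.
#' @param verbose Emit progress messages.
#' @return A report list with per-stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL, fd_threshold = 0.55,
                         n_components = 3, alpha = 1000, n_trials = 5,
                         verbose = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  say <- function(...) if (verbose) message("[gradosc] ", ...)
  say("generating cohort (seed ", config$seed, ")")
  cohort <- make_cohort(config)
  n <- length(cohort$subjects)
  say("QC: framewise displacement filter at ", fd_threshold, " mm")
  fd <- qc_fd_filter(cohort$metadata, fd_threshold)
  keep <- which(!fd$excluded)
  say(sum(fd$excluded), " scan(s) excluded for motion")
  say("computing per-subject FC")
  fc_list <- lapply(cohort$subjects[keep], function(s) fc_direct(s$timeseries))
  fc_edges <- t(vapply(fc_list, edge_vector,
                       numeric(length(edge_vector(fc_list[[1]])))))
  qc_pca <- qc_fc_pca_outliers(fc_edges)
  keep2 <- keep[!qc_pca$outlier]
  say(sum(qc_pca$outlier), " scan(s) flagged as FC outliers")
  excluded <- data.frame(
    subject_id = cohort$metadata$subject_id,
    excluded = !(seq_len(n) %in% keep2),
    reason = ifelse(fd$excluded, fd$reason,
                    ifelse(seq_len(n) %in% keep2, "", "FC PCA outlier")),
    stringsAsFactors = FALSE)
  analyzed <- keep2
  say(length(analyzed), " of ", n, " scans analyzed")
  ## normative pool: severity-0 subjects that passed QC
  pool_idx <- intersect(analyzed, which(cohort$metadata$severity == 0))
  if (length(pool_idx) < 2) pool_idx <- analyzed
  say("fitting gradient basis on ", length(pool_idx), " normative scans")
  basis <- fit_gradient_basis(lapply(cohort$subjects[pool_idx],
                                     `[[`, "timeseries"),
                              k = config$n_gradients)
  say("projecting cohort and fitting oscillator models")
  gts_list <- lapply(cohort$subjects[analyzed], function(s)
    project_timeseries(s$timeseries, basis))
  fits <- lapply(gts_list, fit_oscillator)
  metrics <- t(vapply(fits, eigen_metrics, angle_convention = "absolute",
                      numeric(config$n_gradients +
                                config$n_gradients * (config$n_gradients - 1) / 2)))
  moments <- t(vapply(gts_list, gradient_moments, numeric(ncol(metrics))))
  mm_cor <- metrics_variance_correlation(metrics, moments,
                                         min_subjects = min(25, nrow(metrics)))
  say("PLSR structure-function components")
  fc_edges2 <- t(vapply(cohort$subjects[analyzed], function(s)
    edge_vector(fc_direct(s$timeseries)), numeric(ncol(fc_edges))))
  atrophy <- cohort$atrophy[analyzed, , drop = FALSE]
  plsr <- fit_plsr_components(atrophy, fc_edges2, n_components)
  pca <- atrophy_pca_scores(atrophy, n_components)
  say("cross-validated ridge function scores")
  labels <- cohort$metadata$diagnosis[analyzed]
  ridge <- ridge_function_scores(pca$scores, fc_edges2, labels,
                                 alpha = alpha, n_trials = n_trials)
  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_input = n, n_analyzed = length(analyzed),
    exclusions = excluded,
    qc_fd = fd, qc_fc_pca = qc_pca,
    basis = basis,
    plsr = plsr, atrophy_pca = pca, ridge = ridge,
    eigen_metrics = metrics, gradient_moments = moments,
    metric_moment_correlation = mm_cor,
    scores_table = data.frame(
      cohort$metadata[analyzed, ],
      structure_score = plsr$structure_scores,
      function_score = ridge$function_scores,
      stringsAsFactors = FALSE))
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

## md5 of the serialized generator parameters, for provenance stamping
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[!(names(config) %in% c("basis", "atrophy_patterns",
                                        "baseline_position_coeffs",
                                        "baseline_velocity_coeffs"))], f)
  unname(tools::md5sum(f))
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = report$seed, config_hash = report$config_hash)
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(report$scores_table, stamp),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(report$eigen_metrics),
                   file.path(out_dir, "eigen_metrics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(report$gradient_moments),
                   file.path(out_dir, "gradient_moments.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(report$metric_moment_correlation$correlation),
                   file.path(out_dir, "metric_moment_correlation.csv"),
                   row.names = FALSE)
  summary <- c(stamp, list(
    n_input = report$n_input,
    n_analyzed = report$n_analyzed,
    n_excluded = report$n_input - report$n_analyzed,
    plsr_atrophy_variance = report$plsr$atrophy_variance_explained,
    plsr_score_correlation = report$plsr$score_correlation,
    median_corresponding_r =
      report$metric_moment_correlation$median_corresponding,
    median_noncorresponding_r =
      report$metric_moment_correlation$median_noncorresponding))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
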