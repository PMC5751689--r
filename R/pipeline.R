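#' Run the full network-classification pipeline
#'
#' Orchestrates every stage end to end: low-pass preprocessing and optional
#' task-window extraction, per-subject Pearson correlation, the sparsity
#' sweep with nodal metric profiles, group-difference feature selection, and
#' leave-one-out SVM classification with accuracy / sensitivity /
#' specificity reporting. Identical inputs and configuration yield an
#' identical report.
#'
#' Input is one of:
#' * `cohort` — an in-memory [simulate_cohort()] result;
#' * `manifest` — an `fnirs_manifest` tibble whose `path` column points at
#'   recording files;
#' * `spec` — a [cohort_spec()], which is simulated first.
#'
#' Selection modes: `"fold"` (default; the scan is rerun inside every
#' training fold — leakage-free), `"scan"` (one whole-sample scan before
#' LOOCV; optimistic, since the choice sees test labels) and `"forced"`
#' (classify `choice` directly, e.g. `list(metric = "degree", sparsity =
#' 0.21)`).
#'
#' @param cohort,manifest,spec The input cohort (exactly one non-NULL).
#' @param cutoff_hz,order Low-pass filter settings (see [lowpass_filter()]).
#' @param window_mode `"full"` (default) or `"task_only"` segment for the
#'   correlation (see [extract_window()]).
#' @param task [task_window()] geometry used when `window_mode =
#'   "task_only"`.
#' @param grid Sparsity grid (default [default_sparsity_grid()]).
#' @param threshold_mode `"sparsity"` or `"raw"` (see [threshold_sweep()]).
#' @param selection `"fold"`, `"scan"` or `"forced"`.
#' @param choice Forced `(metric, sparsity)` list for `selection =
#'   "forced"`.
#' @param alpha Scan significance level.
#' @param params [svm_params()].
#' @param out_dir Optional directory; when given, per-subject correlation
#'   matrices, the feature tensor, the selection score table and the report
#'   JSON are written there.
#' @return An `fnirs_pipeline` list: `report` (`fnirs_loocv`), `scan`
#'   (`fnirs_scan` or NULL for forced selection), `tensor`
#'   (`fnirs_tensor`), `features` (the classified slice for non-fold
#'   modes) and `config`.
#' @export
run_pipeline <- function(cohort = NULL, manifest = NULL, spec = NULL,
                         cutoff_hz = 0.5, order = 4L,
                         window_mode = c("full", "task_only"),
                         task = task_window(),
                         grid = default_sparsity_grid(),
                         threshold_mode = c("sparsity", "raw"),
                         selection = c("fold", "scan", "forced"),
                         choice = list(metric = "degree", sparsity = 0.21),
                         alpha = 0.05, params = svm_params(),
                         out_dir = NULL) {
  window_mode <- match.arg(window_mode)
  threshold_mode <- match.arg(threshold_mode)
  selection <- match.arg(selection)
  if (!is.null(spec) && is.null(cohort)) cohort <- simulate_cohort(spec)
  recordings <- if (!is.null(cohort)) {
    cohort$recordings
  } else if (!is.null(manifest)) {
    purrr::pmap(
      manifest[, c("subject_id", "group", "signal_kind", "path")],
      function(subject_id, group, signal_kind, path) {
        read_recording(path, sampling_rate_hz = 10, subject_id = subject_id,
                       group = group, signal_kind = signal_kind)
      }
    )
  } else {
    abort("Provide one of `cohort`, `manifest` or `spec`.")
  }

  pre <- purrr::map(recordings, function(rec) {
    extract_window(lowpass_filter(rec, cutoff_hz, order), task, window_mode)
  })
  tensor <- feature_tensor(pre, grid, mode = threshold_mode)

  scan <- NULL
  if (selection == "fold") {
    report <- loocv_svm(params = params, selection = "fold", tensor = tensor,
                        alpha = alpha)
    scan <- group_difference_scan(tensor, alpha)
  } else {
    if (selection == "scan") {
      scan <- group_difference_scan(tensor, alpha)
      choice <- list(metric = scan$chosen_metric,
                     sparsity = scan$chosen_sparsity)
    }
    feats <- select_feature_vector(tensor, choice$metric, choice$sparsity)
    report <- loocv_svm(features = feats, params = params,
                        selection = "fixed")
  }

  config <- list(
    cutoff_hz = cutoff_hz, order = order, window_mode = window_mode,
    grid = grid, threshold_mode = threshold_mode, selection = selection,
    choice = if (selection == "forced") choice else NULL, alpha = alpha,
    params = unclass(params)
  )
  out <- structure(
    list(report = report, scan = scan, tensor = tensor, config = config),
    class = "fnirs_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(out, pre, out_dir)
  out
}

write_pipeline_artifacts <- function(pipeline, recordings, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (rec in recordings) {
    write_matrix(correlation_matrix(rec),
                 file.path(out_dir, sprintf("corr_%s.tsv", rec$subject_id)))
  }
  readr::write_tsv(pipeline$tensor, file.path(out_dir, "feature_tensor.tsv"))
  if (!is.null(pipeline$scan)) {
    readr::write_tsv(pipeline$scan$score_table,
                     file.path(out_dir, "selection_scores.tsv"))
    jsonlite::write_json(glance(pipeline$scan),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  write_report(pipeline$report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' @export
print.fnirs_pipeline <- function(x, ...) {
  cat(sprintf("<fnirs_pipeline> selection = %s, %d sparsity levels\n",
              x$config$selection, length(x$config$grid)))
  print(x$report)
  invisible(x)
}

#' @method glance fnirs_pipeline
#' @export
glance.fnirs_pipeline <- function(x, ...) glance(x$report)

#' @method tidy fnirs_pipeline
#' @export
tidy.fnirs_pipeline <- function(x, ...) tidy(x$report)
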