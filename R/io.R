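#' Read one subject's multichannel recording from delimited text
#'
#' Files are plain comma- or tab-separated matrices with one row per time
#' sample and one column per channel, optionally preceded by a header row of
#' channel labels. The delimiter is auto-detected from the first line; the
#' decimal separator is always the point. Data are transposed on read so the
#' returned recording is channels x samples.
#'
#' @param path Path to the delimited text file.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_labels Optional channel labels; overrides any header row.
#' @param subject_id,group,signal_kind Metadata attached to the recording
#'   (see [recording()]).
#'
#' @return An [recording()] object (`fnirs_recording`).
#' @export
read_recording <- function(path, sampling_rate_hz, channel_labels = NULL,
                           subject_id = basename(path), group = 0L,
                           signal_kind = "oxy") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(sprintf("Empty recording file: %s", path))
  sep <- detect_delimiter(first)

  counts <- count.fields(path, sep = sep, blank.lines.skip = TRUE)
  if (length(counts) == 0L) abort(sprintf("Empty recording file: %s", path))
  if (length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1])[1]
    abort(sprintf(
      "Ragged rows in %s: row %d has %d fields, expected %d.",
      path, bad, counts[bad], counts[1]
    ))
  }

  header_tokens <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(header_tokens)))
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           skip = if (has_header) 1L else 0L,
                           colClasses = "character",
                           blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) abort(sprintf("No data rows in %s", path))
  values <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  values <- matrix(values, nrow = nrow(raw))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-numeric value '%s' in %s at data row %d, column %d.",
      raw[idx[1], idx[2]], path, idx[1], idx[2]
    ))
  }
  if (is.null(channel_labels) && has_header) {
    channel_labels <- trimws(header_tokens)
  }
  recording(t(values), sampling_rate_hz = sampling_rate_hz,
            channel_labels = channel_labels, subject_id = subject_id,
            group = group, signal_kind = signal_kind)
}

detect_delimiter <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read a cohort manifest
#'
#' A manifest lists the subjects of a study: columns `subject_id`, `group`,
#' `signal_kind`, `path` in CSV form, or the YAML equivalent (a list of
#' records with those fields). Group tokens may be `1`/`-1`,
#' `patient`/`control`, `schizophrenia`/`healthy`.
#'
#' @param path Manifest file (`.csv`, `.yaml` or `.yml`).
#' @param check_paths Verify that every recording file exists (default TRUE).
#' @return A tibble with columns `subject_id`, `group` (integer +1/-1),
#'   `signal_kind`, `path`, of class `fnirs_manifest`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    records <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(records, tibble::as_tibble))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  }
  as_manifest(df, base_dir = dirname(path), check_paths = check_paths)
}

#' Validate a data frame as a cohort manifest
#'
#' @param df Data frame with columns `subject_id`, `group`, `signal_kind`,
#'   `path`.
#' @param base_dir Directory against which relative paths are resolved.
#' @param check_paths Verify that referenced files exist.
#' @return A validated `fnirs_manifest` tibble.
#' @export
as_manifest <- function(df, base_dir = ".", check_paths = FALSE) {
  needed <- c("subject_id", "group", "signal_kind", "path")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Manifest is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) abort("Manifest contains no subjects.")
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    abort(sprintf("Duplicate subject_id in manifest: %s",
                  paste(dup, collapse = ", ")))
  }
  out <- tibble::tibble(
    subject_id = as.character(df$subject_id),
    group = unname(vapply(df$group, parse_group, integer(1))),
    signal_kind = as.character(df$signal_kind),
    path = as.character(df$path)
  )
  bad_kind <- setdiff(unique(out$signal_kind), c("oxy", "deoxy", "total"))
  if (length(bad_kind)) {
    abort(sprintf("Unknown signal_kind: %s", paste(bad_kind, collapse = ", ")))
  }
  if (check_paths) {
    resolved <- ifelse(file.exists(out$path), out$path,
                       file.path(base_dir, out$path))
    absent <- !file.exists(resolved)
    if (any(absent)) {
      abort(sprintf("Recording file(s) not found: %s",
                    paste(out$path[absent], collapse = ", ")))
    }
    out$path <- resolved
  }
  class(out) <- c("fnirs_manifest", class(out))
  out
}

#' @export
print.fnirs_manifest <- function(x, ...) {
  cat(sprintf("<fnirs_manifest> %d subjects (%d patients, %d controls)\n",
              nrow(x), sum(x$group == 1), sum(x$group == -1)))
  NextMethod()
}

#' Cohort composition of a manifest
#' @param manifest An `fnirs_manifest`.
#' @return Named integer vector `c(patients = ..., controls = ...)`.
#' @export
manifest_counts <- function(manifest) {
  c(patients = sum(manifest$group == 1L),
    controls = sum(manifest$group == -1L))
}

#' Write / read a labelled square matrix as TSV
#'
#' Matrices (correlation or adjacency) are stored as tab-separated text with a
#' header row and a leading column of channel labels, at full double
#' precision so that a read/write round trip is lossless to at least 12
#' significant digits.
#'
#' @param matrix Square numeric matrix.
#' @param path Output file.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   the labelled matrix.
#' @export
write_matrix <- function(matrix, path) {
  if (nrow(matrix) != ncol(matrix)) {
    abort(sprintf("Matrix must be square; got %d x %d.",
                  nrow(matrix), ncol(matrix)))
  }
  labels <- rownames(matrix) %||% sprintf("CH%02d", seq_len(nrow(matrix)))
  lines <- c(
    paste(c("channel", labels), collapse = "\t"),
    vapply(seq_len(nrow(matrix)), function(i) {
      paste(c(labels[i], format(matrix[i, ], digits = 17, trim = TRUE,
                                scientific = FALSE)), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("File %s does not contain a square matrix.", path))
  }
  m
}

#' Write / read a classification performance report as JSON
#'
#' The report JSON records the confusion counts, the accuracy / sensitivity /
#' specificity, the selected feature (metric and sparsity) and the per-fold
#' predictions, so a cross-validation run can be audited or reloaded.
#'
#' @param report An `fnirs_loocv` object (see [loocv_svm()]).
#' @param path Output file.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   an `fnirs_loocv` object.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fnirs_loocv"))
  payload <- list(
    confusion = as.list(report$confusion),
    metrics = list(accuracy = report$accuracy,
                   sensitivity = report$sensitivity,
                   specificity = report$specificity),
    selection = report$selection,
    folds = report$folds
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- tibble::as_tibble(payload$folds)
  new_loocv_result(
    folds = folds,
    confusion = unlist(payload$confusion)[c("TP", "FN", "FP", "TN")],
    selection = payload$selection
  )
}
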