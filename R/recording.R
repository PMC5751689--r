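#' Construct an fNIRS recording
#'
#' A recording holds one subject's multichannel hemodynamic time series as a
#' channels x samples matrix together with its acquisition metadata. Group
#' labels follow the convention `+1` = patient, `-1` = healthy control, `0` =
#' unknown.
#'
#' @param data Numeric matrix, channels x samples (C x N, N >= 2).
#' @param sampling_rate_hz Sampling rate in Hz (positive; 10 Hz for a typical
#'   ETG-4000 acquisition).
#' @param channel_labels Character vector of unique channel names; defaults to
#'   `CH01 ... CHxx`.
#' @param subject_id Subject identifier string.
#' @param group Group code: `1` (patient), `-1` (control) or `0` (unknown).
#'   Tokens such as `"patient"`, `"schizophrenia"`, `"control"`, `"healthy"`
#'   are also accepted.
#' @param signal_kind One of `"oxy"`, `"deoxy"`, `"total"`.
#'
#' @return An object of class `fnirs_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(20), nrow = 2), sampling_rate_hz = 10)
#' n_channels(rec)
recording <- function(data, sampling_rate_hz, channel_labels = NULL,
                      subject_id = "S", group = 0L, signal_kind = "oxy") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2) {
    abort("A recording needs at least 2 time samples per channel.")
  }
  if (anyNA(data)) abort("Recording data must not contain missing values.")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a single positive number.")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    abort(sprintf("%d channel labels supplied for %d channels.",
                  length(channel_labels), nrow(data)))
  }
  if (anyDuplicated(channel_labels)) {
    abort("Channel labels must be unique.")
  }
  rownames(data) <- channel_labels
  signal_kind <- match.arg(signal_kind, c("oxy", "deoxy", "total"))
  structure(
    list(
      subject_id = as.character(subject_id),
      group = parse_group(group),
      signal_kind = signal_kind,
      sampling_rate_hz = sampling_rate_hz,
      channel_labels = channel_labels,
      data = data
    ),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "<fnirs_recording> %s | %s-Hb | %d channels x %d samples @ %g Hz | group %s\n",
    x$subject_id, x$signal_kind, n_channels(x), n_samples(x),
    x$sampling_rate_hz, group_token(x$group)
  ))
  invisible(x)
}

#' Number of channels / samples in a recording
#' @param rec An `fnirs_recording`.
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

# Map group tokens to the +1 / -1 / 0 integer code.
parse_group <- function(group) {
  if (is.numeric(group)) {
    if (!group %in% c(1, -1, 0)) {
      abort("Numeric group codes must be 1 (patient), -1 (control) or 0.")
    }
    return(as.integer(group))
  }
  token <- tolower(trimws(as.character(group)))
  switch(token,
    "1" = , "+1" = , "patient" = , "schizophrenia" = , "positive" = 1L,
    "-1" = , "control" = , "healthy" = , "negative" = -1L,
    "0" = , "unknown" = 0L,
    abort(sprintf("Unknown group token '%s'.", group))
  )
}

group_token <- function(code) {
  c(`-1` = "control", `0` = "unknown", `1` = "patient")[[as.character(code)]]
}

#' Convert a recording to a tidy tibble
#'
#' @param x An `fnirs_recording`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time_s`, `value`.
#' @method tidy fnirs_recording
#' @export
tidy.fnirs_recording <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_labels, each = n_samples(x)),
    time_s = rep((seq_len(n_samples(x)) - 1) / x$sampling_rate_hz,
                 times = n_channels(x)),
    value = as.vector(t(x$data))
  )
}

#' Combine oxy- and deoxy-hemoglobin recordings into a total-Hb recording
#'
#' Total hemoglobin change is the per-sample sum of the oxygenated and
#' deoxygenated hemoglobin changes.
#'
#' @param oxy,deoxy `fnirs_recording` objects with identical geometry.
#' @return An `fnirs_recording` with `signal_kind = "total"`.
#' @export
total_recording <- function(oxy, deoxy) {
  stopifnot(inherits(oxy, "fnirs_recording"), inherits(deoxy, "fnirs_recording"))
  if (!identical(dim(oxy$data), dim(deoxy$data))) {
    abort("oxy and deoxy recordings must have identical channel/sample counts.")
  }
  out <- oxy
  out$data <- oxy$data + deoxy$data
  out$signal_kind <- "total"
  out
}

#' @method autoplot fnirs_recording
#' @export
autoplot.fnirs_recording <- function(object, channels = head(object$channel_labels, 6), ...) {
  df <- dplyr::filter(tidy(object), .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "concentration change (a.u.)",
                  title = sprintf("%s (%s-Hb)", object$subject_id, object$signal_kind))
}
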