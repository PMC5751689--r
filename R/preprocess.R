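#' One-sided power spectrum of every channel
#'
#' Computes the discrete Fourier transform of each channel and returns the
#' one-sided power spectrum, used to check where the hemodynamic signal lives
#' before choosing a low-pass cutoff (fNIRS hemodynamics are essentially
#' confined below 0.5 Hz; cardiac and instrument noise sit above).
#'
#' @param rec An `fnirs_recording` with at least 2 samples.
#' @return A tibble of class `fnirs_spectrum` with columns `channel`,
#'   `frequency_hz` (0 to Nyquist, resolution `sampling_rate / N`) and
#'   `power` (squared DFT modulus / N).
#' @export
#' @examples
#' rec <- recording(matrix(sin(2 * pi * 0.2 * (0:999) / 10), nrow = 1), 10)
#' sp <- power_spectrum(rec)
#' sp$frequency_hz[which.max(sp$power)] # 0.2 Hz
power_spectrum <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  n <- n_samples(rec)
  if (n < 2) abort("Spectrum needs at least 2 samples.")
  n_keep <- floor(n / 2) + 1L
  freqs <- (seq_len(n_keep) - 1) * rec$sampling_rate_hz / n
  pw <- apply(rec$data, 1, function(x) Mod(fft(x))[seq_len(n_keep)]^2 / n)
  out <- tibble::tibble(
    channel = rep(rec$channel_labels, each = n_keep),
    frequency_hz = rep(freqs, times = n_channels(rec)),
    power = as.vector(pw)
  )
  class(out) <- c("fnirs_spectrum", class(out))
  out
}

#' @method autoplot fnirs_spectrum
#' @export
autoplot.fnirs_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$frequency_hz, .data$power,
                               group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = "Per-channel power spectrum")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Removes high-frequency noise (cardiac pulsation, instrument noise) from
#' each channel with an order-`order` Butterworth low-pass applied
#' forward-backward, so the effective magnitude response is the square of the
#' single-pass response and the phase response is zero: hemodynamic timing is
#' not shifted and the DC level is preserved. Boundary transients are
#' suppressed by odd-reflection padding of one warm-up length at each end
#' before the two passes.
#'
#' @param rec An `fnirs_recording`.
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.5, below which fNIRS
#'   hemodynamics are concentrated). Must be below the Nyquist frequency.
#' @param order Butterworth order of each pass (default 4).
#' @return A filtered `fnirs_recording` of identical shape.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 0.5, order = 4L) {
  stopifnot(inherits(rec, "fnirs_recording"))
  fs <- rec$sampling_rate_hz
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff_hz must lie in (0, Nyquist = %g Hz).", fs / 2))
  }
  if (order < 1) abort("Filter order must be a positive integer.")
  pad <- filter_pad_length(fs, cutoff_hz, order)
  n <- n_samples(rec)
  if (n <= pad) {
    abort(sprintf(
      "Recording too short to filter: need more than %d samples (have %d).",
      pad, n
    ))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  out <- rec
  out$data <- t(apply(rec$data, 1, filtfilt_reflect, b = bf$b, a = bf$a,
                      pad = pad))
  dimnames(out$data) <- dimnames(rec$data)
  out
}

# Warm-up length: three time constants of the cutoff period, bounded by order.
filter_pad_length <- function(fs, cutoff_hz, order) {
  max(3L * 2L * as.integer(order), ceiling(3 * fs / cutoff_hz))
}

# Forward-backward IIR pass with odd-reflection padding at both ends. Each
# pass filters the deviation from the boundary value (steady-state start), so
# a constant input passes through exactly and start-up transients scale with
# the local signal deviation, not its absolute level.
filtfilt_reflect <- function(x, b, a, pad) {
  n <- length(x)
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(front, x, back)
  one_pass <- function(z) {
    as.numeric(signal::filter(b, a, z - z[1])) + z[1]
  }
  y <- rev(one_pass(rev(one_pass(ext))))
  y[seq(pad + 1, pad + n)]
}

#' Task window of a block-design acquisition
#'
#' The acquisition protocol is a single task block: a pre-scan, a waiting
#' period, the task itself, and a post-task baseline (defaults 5 / 25 / 70 /
#' 50 s, i.e. 150 s in total).
#'
#' @param pre_s,wait_s,task_s,post_s Segment durations in seconds.
#' @return A `task_window` list.
#' @export
task_window <- function(pre_s = 5, wait_s = 25, task_s = 70, post_s = 50) {
  vals <- c(pre_s = pre_s, wait_s = wait_s, task_s = task_s, post_s = post_s)
  if (any(vals < 0)) abort("Task window durations must be nonnegative.")
  structure(as.list(vals), class = "task_window")
}

#' Extract the analysis segment of a recording
#'
#' `mode = "full"` returns the recording unchanged; `mode = "task_only"`
#' keeps only the task block, i.e. the half-open sample interval
#' `[(pre + wait) * fs, (pre + wait + task) * fs)` in 0-based indexing.
#'
#' @param rec An `fnirs_recording`.
#' @param window A [task_window()].
#' @param mode `"full"` or `"task_only"`.
#' @return An `fnirs_recording` (possibly shortened).
#' @export
extract_window <- function(rec, window = task_window(),
                           mode = c("full", "task_only")) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(window, "task_window"))
  mode <- match.arg(mode)
  fs <- rec$sampling_rate_hz
  task_end <- (window$pre_s + window$wait_s + window$task_s) * fs
  if (mode == "full") {
    return(rec)
  }
  start0 <- round((window$pre_s + window$wait_s) * fs) # 0-based, inclusive
  end0 <- round(task_end)                              # 0-based, exclusive
  if (end0 > n_samples(rec)) {
    abort(sprintf("Task window end (sample %d) exceeds recording length %d.",
                  end0, n_samples(rec)))
  }
  out <- rec
  out$data <- rec$data[, (start0 + 1):end0, drop = FALSE]
  out
}
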