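#' Specification of a synthetic two-group fNIRS cohort
#'
#' Describes a simulated case-control study with known ground truth. The
#' defaults mirror a 52-channel prefrontal acquisition at 10 Hz with a single
#' 5/25/70/50 s block task, 42 patients and 34 controls. Channels are
#' organised in blocks (default four blocks of 13) with strong within-block
#' and weak between-block baseline correlation; the patient group's
#' within-block correlation is attenuated by `connectivity_attenuation`, and
#' its task-locked hemodynamic response amplitude is reduced
#' (`hrf_amplitude_patient < hrf_amplitude_control`), emulating the
#' hypoactivation and disrupted prefrontal connectivity reported in
#' schizophrenia.
#'
#' @param n_patients,n_controls Group sizes (defaults 42 and 34).
#' @param n_channels Channel count (default 52).
#' @param sampling_rate_hz Sampling rate (default 10 Hz).
#' @param task [task_window()] block design (defaults 5/25/70/50 s).
#' @param n_blocks Number of correlation blocks the channels split into
#'   (default 4).
#' @param within_block_r Control-group within-block correlation (default
#'   0.6).
#' @param between_block_r Between-block correlation (default 0.1).
#' @param connectivity_attenuation Fractional reduction of the patient
#'   group's within-block correlation, in \[0, 1\] (default 0.12, i.e. 0.6 ->
#'   0.528).
#' @param hrf_amplitude_control,hrf_amplitude_patient Peak activation
#'   amplitudes, in baseline-SD units (defaults 1.0 and 0.8).
#' @param active_blocks Which correlation blocks receive the task response
#'   (default the first two, an "anterior" subset); remaining blocks get
#'   `inactive_gain` of it.
#' @param inactive_gain Activation gain of non-active blocks (default 0.3).
#' @param noise_sd Baseline (correlated) signal SD (default 1).
#' @param drift_amplitude Amplitude of a slow 0.02 Hz physiological drift
#'   (default 0.5).
#' @param hf_noise_sd SD of the additive white measurement noise, the
#'   component carrying power above 0.5 Hz (default 1.2).
#' @param seed Master seed; every subject's draw is derived from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 42L, n_controls = 34L, n_channels = 52L,
                        sampling_rate_hz = 10, task = task_window(),
                        n_blocks = 4L, within_block_r = 0.6,
                        between_block_r = 0.1,
                        connectivity_attenuation = 0.12,
                        hrf_amplitude_control = 1.0,
                        hrf_amplitude_patient = 0.8,
                        active_blocks = c(1L, 2L), inactive_gain = 0.3,
                        noise_sd = 1, drift_amplitude = 0.5,
                        hf_noise_sd = 1.2, seed = 42L) {
  if (n_patients < 0 || n_controls < 0) abort("Group sizes must be nonnegative.")
  if (connectivity_attenuation < 0 || connectivity_attenuation > 1) {
    abort("`connectivity_attenuation` must lie in [0, 1].")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_controls = as.integer(n_controls),
      n_channels = as.integer(n_channels),
      sampling_rate_hz = sampling_rate_hz,
      task = task,
      n_blocks = as.integer(n_blocks),
      within_block_r = within_block_r,
      between_block_r = between_block_r,
      connectivity_attenuation = connectivity_attenuation,
      hrf_amplitude_control = hrf_amplitude_control,
      hrf_amplitude_patient = hrf_amplitude_patient,
      active_blocks = as.integer(active_blocks),
      inactive_gain = inactive_gain,
      noise_sd = noise_sd,
      drift_amplitude = drift_amplitude,
      hf_noise_sd = hf_noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Channel -> block assignment (near-equal contiguous blocks).
block_assignment <- function(spec) {
  sort(rep_len(seq_len(spec$n_blocks), spec$n_channels))
}

#' Target correlation structure of one group
#'
#' Builds the block-structured correlation matrix the baseline signal of a
#' group is drawn from: `within_block_r` inside blocks (attenuated by
#' `connectivity_attenuation` for patients), `between_block_r` elsewhere,
#' unit diagonal.
#'
#' @param spec A [cohort_spec()].
#' @param group `1` (patient) or `-1` (control).
#' @return A positive-definite correlation matrix of class `fnirs_cor`.
#' @export
build_group_correlation <- function(spec, group) {
  group <- parse_group(group)
  within <- spec$within_block_r *
    (if (group == 1L) 1 - spec$connectivity_attenuation else 1)
  blocks <- block_assignment(spec)
  same <- outer(blocks, blocks, "==")
  r <- ifelse(same, within, spec$between_block_r)
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort(sprintf(
      "Requested block correlation matrix is not positive definite (min eigenvalue %.3g).",
      min(ev)
    ))
  }
  dimnames(r) <- rep(list(sprintf("CH%02d", seq_len(spec$n_channels))), 2)
  class(r) <- c("fnirs_cor", class(r))
  r
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma HRF (response peak near 6 s, undershoot near
#' 16 s), sampled at `dt`-second resolution and normalised to unit peak.
#'
#' @param t_max Support length in seconds (default 32).
#' @param dt Sample spacing in seconds.
#' @return Numeric vector of HRF samples.
#' @export
hrf_double_gamma <- function(t_max = 32, dt = 0.1) {
  t <- seq(0, t_max, by = dt)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# Task regressor: boxcar over the task block convolved with the HRF.
task_regressor <- function(spec) {
  fs <- spec$sampling_rate_hz
  tw <- spec$task
  n <- round((tw$pre_s + tw$wait_s + tw$task_s + tw$post_s) * fs)
  box <- numeric(n)
  on <- round((tw$pre_s + tw$wait_s) * fs)
  off <- round((tw$pre_s + tw$wait_s + tw$task_s) * fs)
  box[(on + 1):off] <- 1
  h <- hrf_double_gamma(dt = 1 / fs)
  reg <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
  reg / max(reg)
}

#' Simulate one subject's multichannel recording
#'
#' The signal model is: correlated Gaussian baseline (target correlation
#' imposed through its Cholesky factor, SD `noise_sd`) + task-locked
#' activation (boxcar convolved with the double-gamma HRF, scaled by the
#' group amplitude and the per-block activation gain) + a slow sinusoidal
#' drift with random phase per channel + white measurement noise of SD
#' `hf_noise_sd`. Reproducible: the same `(spec$seed, subject_seed)` pair
#' yields an identical recording.
#'
#' @param target Target correlation matrix (see [build_group_correlation()]).
#' @param spec A [cohort_spec()].
#' @param group `1` or `-1`.
#' @param subject_seed Per-subject RNG seed.
#' @param subject_id Identifier for the generated recording.
#' @return An `fnirs_recording` of `n_channels` x `duration * rate` samples.
#' @export
simulate_recording <- function(target, spec, group, subject_seed,
                               subject_id = "SIM") {
  group <- parse_group(group)
  fs <- spec$sampling_rate_hz
  reg <- task_regressor(spec)
  n <- length(reg)
  c_ch <- spec$n_channels
  l_chol <- chol(unclass(target))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(subject_seed)
  baseline <- t(matrix(rnorm(n * c_ch), n, c_ch) %*% l_chol) * spec$noise_sd
  amp <- if (group == 1L) spec$hrf_amplitude_patient else
    spec$hrf_amplitude_control
  gains <- ifelse(block_assignment(spec) %in% spec$active_blocks,
                  1, spec$inactive_gain)
  activation <- outer(gains * amp, reg)
  phases <- runif(c_ch, 0, 2 * pi)
  t_s <- (seq_len(n) - 1) / fs
  drift <- spec$drift_amplitude *
    sin(outer(phases, rep(1, n)) + 2 * pi * 0.02 * outer(rep(1, c_ch), t_s))
  hf <- matrix(rnorm(n * c_ch, sd = spec$hf_noise_sd), c_ch, n)
  recording(baseline + activation + drift + hf, sampling_rate_hz = fs,
            channel_labels = rownames(target),
            subject_id = subject_id, group = group, signal_kind = "oxy")
}

#' Simulate a full two-group cohort with ground truth
#'
#' Draws `n_patients + n_controls` recordings (patients first), each from its
#' group's target correlation structure, with per-subject seeds derived
#' deterministically from the master seed. Optionally writes the cohort to
#' disk as per-subject CSV files plus a `manifest.csv`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory, or `NULL` (default) to keep the cohort in
#'   memory only.
#' @return A list of class `fnirs_cohort` with elements `recordings` (list
#'   of `fnirs_recording`), `manifest` (an `fnirs_manifest` tibble; `path` is
#'   `NA` for in-memory cohorts) and `ground_truth` (target correlation
#'   matrices, group amplitudes and the active channel set).
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  targets <- list(
    patient = build_group_correlation(spec, 1L),
    control = build_group_correlation(spec, -1L)
  )
  n_total <- spec$n_patients + spec$n_controls
  if (n_total == 0) abort("Cohort must contain at least one subject.")
  groups <- c(rep(1L, spec$n_patients), rep(-1L, spec$n_controls))
  ids <- sprintf("S%03d", seq_len(n_total))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  recordings <- purrr::map(seq_len(n_total), function(i) {
    target <- if (groups[i] == 1L) targets$patient else targets$control
    simulate_recording(target, spec, groups[i], subject_seeds[i], ids[i])
  })
  manifest <- tibble::tibble(
    subject_id = ids,
    group = groups,
    signal_kind = "oxy",
    path = NA_character_
  )
  blocks <- block_assignment(spec)
  ground_truth <- list(
    patient_correlation = targets$patient,
    control_correlation = targets$control,
    hrf_amplitudes = c(patient = spec$hrf_amplitude_patient,
                       control = spec$hrf_amplitude_control),
    active_channels = rownames(targets$control)[blocks %in% spec$active_blocks],
    subject_seeds = subject_seeds
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(ids, ".csv"))
    purrr::walk2(recordings, manifest$path, function(rec, p) {
      df <- as.data.frame(t(rec$data))
      names(df) <- rec$channel_labels
      readr::write_csv(df, p)
    })
    readr::write_csv(
      tibble::tibble(subject_id = ids,
                     group = groups,
                     signal_kind = "oxy",
                     path = basename(manifest$path)),
      file.path(dir, "manifest.csv")
    )
    write_matrix(targets$patient, file.path(dir, "target_patient.tsv"))
    write_matrix(targets$control, file.path(dir, "target_control.tsv"))
  }
  class(manifest) <- c("fnirs_manifest", class(manifest))
  structure(
    list(recordings = recordings, manifest = manifest,
         ground_truth = ground_truth, spec = spec),
    class = "fnirs_cohort"
  )
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  cat(sprintf(
    "<fnirs_cohort> %d patients + %d controls | %d channels x %d samples @ %g Hz (seed %d)\n",
    x$spec$n_patients, x$spec$n_controls, x$spec$n_channels,
    n_samples(x$recordings[[1]]), x$spec$sampling_rate_hz, x$spec$seed
  ))
  invisible(x)
}
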