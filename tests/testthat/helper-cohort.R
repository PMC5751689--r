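# Small in-code fixtures shared across test files.

sine_recording <- function(freqs, fs = 10, n = 1000, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  data <- do.call(rbind, lapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  recording(data, sampling_rate_hz = fs)
}

write_temp_recording <- function(mat, sep = ",", header = NULL) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  lines <- apply(mat, 1, paste, collapse = sep)
  if (!is.null(header)) lines <- c(paste(header, collapse = sep), lines)
  writeLines(lines, path)
  path
}

# A tiny labelled feature tibble usable with loocv_svm(selection = "fixed").
make_features <- function(x, groups, metric = "degree", sparsity = 0.21) {
  df <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
  names(df) <- sprintf("CH%02d", seq_len(ncol(x)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(nrow(x))),
                   group = as.integer(groups)),
    df
  )
  structure(out, class = c("fnirs_features", class(tibble::tibble())),
            metric = metric, sparsity = sparsity)
}

# Synthetic feature tensor: Gaussian noise over the full metric x sparsity x
# channel grid, with an optional mean shift planted for patients at one
# (metric, sparsity) on a subset of channels.
make_tensor <- function(n_pat, n_con, n_channels = 52,
                        grid = default_sparsity_grid(),
                        planted = NULL, effect = 0, n_shift_channels = 10) {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n_pat + n_con)),
    group = c(rep(1L, n_pat), rep(-1L, n_con))
  )
  channels <- sprintf("CH%02d", seq_len(n_channels))
  base <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    metric = c("degree", "clustering", "local_efficiency", "global_efficiency"),
    sparsity = grid,
    channel = channels
  )
  base <- dplyr::left_join(base, subjects, by = "subject_id")
  base$value <- rnorm(nrow(base))
  if (!is.null(planted) && effect != 0) {
    hit <- base$metric == planted$metric &
      abs(base$sparsity - planted$sparsity) < 1e-9 &
      base$channel %in% channels[seq_len(n_shift_channels)] &
      base$group == 1L
    base$value[hit] <- base$value[hit] + effect
  }
  out <- dplyr::relocate(base, "subject_id", "group")
  class(out) <- c("fnirs_tensor", class(out))
  out
}
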