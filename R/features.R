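#' Nodal metrics across the sparsity sweep for one correlation matrix
#'
#' Sweeps the correlation matrix over the sparsity grid and evaluates the
#' four nodal metrics on every resulting network.
#'
#' @param corr Correlation matrix (`fnirs_cor`).
#' @param grid Sparsity grid (default [default_sparsity_grid()]).
#' @param mode `"sparsity"` or `"raw"` thresholding (see [threshold_sweep()]).
#' @return A tibble with columns `sparsity`, `channel`, `metric`, `value`
#'   (4 metrics x levels x channels rows).
#' @export
network_metrics <- function(corr, grid = default_sparsity_grid(),
                            mode = c("sparsity", "raw")) {
  mode <- match.arg(mode)
  sweep_tbl <- threshold_sweep(corr, grid, mode = mode)
  purrr::map2_dfr(sweep_tbl$adjacency, sweep_tbl$level, function(adj, lev) {
    prof <- metric_profile(adj)
    prof$sparsity <- lev
    tidyr::pivot_longer(prof, cols = dplyr::all_of(metric_names()),
                        names_to = "metric", values_to = "value")
  })
}

#' Subjects x metrics x sparsity x channels feature tensor
#'
#' Evaluates [network_metrics()] for every subject of a cohort and stacks the
#' results in long form: one row per subject, metric, sparsity level and
#' channel. This is the object the feature-selection scan operates on.
#'
#' @param recordings List of preprocessed `fnirs_recording` objects (each
#'   carrying its group label).
#' @param grid Sparsity grid.
#' @param mode Thresholding mode (see [threshold_sweep()]).
#' @return A tibble of class `fnirs_tensor` with columns `subject_id`,
#'   `group`, `sparsity`, `channel`, `metric`, `value`.
#' @export
feature_tensor <- function(recordings, grid = default_sparsity_grid(),
                           mode = c("sparsity", "raw")) {
  mode <- match.arg(mode)
  out <- purrr::map_dfr(recordings, function(rec) {
    nm <- network_metrics(correlation_matrix(rec), grid, mode = mode)
    nm$subject_id <- rec$subject_id
    nm$group <- rec$group
    nm
  })
  out <- dplyr::relocate(out, "subject_id", "group")
  class(out) <- c("fnirs_tensor", class(out))
  out
}

# Internal wide form: subjects x (metric, sparsity, channel) value matrix.
tensor_matrix <- function(tensor) {
  key <- paste(tensor$metric, tensor$sparsity, tensor$channel, sep = "\r")
  subjects <- unique(tensor$subject_id)
  combos <- unique(key)
  x <- matrix(NA_real_, length(subjects), length(combos),
              dimnames = list(subjects, combos))
  x[cbind(match(tensor$subject_id, subjects), match(key, combos))] <-
    tensor$value
  if (anyNA(x)) abort("Feature tensor has missing (subject, feature) entries.")
  parts <- strsplit(combos, "\r", fixed = TRUE)
  index <- tibble::tibble(
    metric = vapply(parts, `[[`, character(1), 1),
    sparsity = as.numeric(vapply(parts, `[[`, character(1), 2)),
    channel = vapply(parts, `[[`, character(1), 3)
  )
  groups <- tensor$group[match(subjects, tensor$subject_id)]
  list(x = x, index = index,
       subjects = tibble::tibble(subject_id = subjects, group = groups))
}

# Vectorised two-sample Welch t-test p-values over the columns of x.
# Columns that are constant in both groups get p = 1 (and a warning upstream).
welch_p_values <- function(x, is_patient) {
  n1 <- sum(is_patient); n2 <- sum(!is_patient)
  x1 <- x[is_patient, , drop = FALSE]
  x2 <- x[!is_patient, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & (m1 == m2)] <- 1
  p[degenerate & (m1 != m2)] <- 0
  attr(p, "n_degenerate") <- sum(degenerate & (m1 == m2))
  p
}

#' Scan all (metric, sparsity) combinations for group differences
#'
#' For every metric and sparsity level, each channel is tested for a
#' patient-vs-control difference with a two-sample Welch t-test; the score of
#' the combination is the number of channels significant at `alpha` (no
#' multiple-testing correction by default, `p_adjust = "bonferroni"` is
#' available). The selected feature is the combination with the highest
#' score; ties are broken deterministically toward the lower sparsity, then
#' the metric order degree < clustering < local_efficiency <
#' global_efficiency.
#'
#' @param tensor An `fnirs_tensor` (see [feature_tensor()]).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param p_adjust `"none"` (default) or `"bonferroni"` across channels
#'   within each combination.
#' @return An object of class `fnirs_scan`: a list with `score_table`
#'   (tibble metric x sparsity x n_significant), `chosen_metric`,
#'   `chosen_sparsity`, `p_values` (per-channel p at the chosen combination)
#'   and `alpha`.
#' @export
group_difference_scan <- function(tensor, alpha = 0.05,
                                  p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  tm <- tensor_matrix(tensor)
  scan_matrix(tm, alpha, p_adjust)
}

# Core scan on the wide form; reused per-fold inside LOOCV.
scan_matrix <- function(tm, alpha, p_adjust = "none", quiet = FALSE) {
  is_patient <- tm$subjects$group == 1L
  if (sum(is_patient) < 2 || sum(!is_patient) < 2) {
    abort("Each group needs at least 2 subjects for the difference scan.")
  }
  p <- welch_p_values(tm$x, is_patient)
  if (!quiet && attr(p, "n_degenerate") > 0) {
    warn(sprintf(
      "%d feature(s) constant across all subjects; their p-values were set to 1.",
      attr(p, "n_degenerate")
    ))
  }
  idx <- tm$index
  idx$p <- as.numeric(p)
  if (p_adjust == "bonferroni") {
    idx <- dplyr::group_by(idx, .data$metric, .data$sparsity)
    idx <- dplyr::mutate(idx, p = stats::p.adjust(.data$p, "bonferroni"))
    idx <- dplyr::ungroup(idx)
  }
  score_table <- dplyr::summarise(
    dplyr::group_by(idx, .data$metric, .data$sparsity),
    n_significant = sum(.data$p < alpha),
    .groups = "drop"
  )
  rank <- order(-score_table$n_significant, score_table$sparsity,
                match(score_table$metric, metric_names()))
  best <- score_table[rank[1], ]
  chosen_p <- dplyr::filter(idx, .data$metric == best$metric,
                            .data$sparsity == best$sparsity)
  structure(
    list(
      score_table = score_table,
      chosen_metric = best$metric,
      chosen_sparsity = best$sparsity,
      n_significant = best$n_significant,
      p_values = chosen_p[, c("channel", "p")],
      alpha = alpha
    ),
    class = "fnirs_scan"
  )
}

#' @export
print.fnirs_scan <- function(x, ...) {
  cat(sprintf(
    "<fnirs_scan> chosen: %s at sparsity %.2f (%d/%d channels significant at alpha = %g)\n",
    x$chosen_metric, x$chosen_sparsity, x$n_significant,
    nrow(x$p_values), x$alpha
  ))
  invisible(x)
}

#' @method tidy fnirs_scan
#' @export
tidy.fnirs_scan <- function(x, ...) x$score_table

#' @method glance fnirs_scan
#' @export
glance.fnirs_scan <- function(x, ...) {
  tibble::tibble(
    chosen_metric = x$chosen_metric,
    chosen_sparsity = x$chosen_sparsity,
    n_significant = x$n_significant,
    alpha = x$alpha
  )
}

#' @method autoplot fnirs_scan
#' @export
autoplot.fnirs_scan <- function(object, ...) {
  ggplot2::ggplot(object$score_table,
                  ggplot2::aes(.data$sparsity, .data$n_significant,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(object$score_table,
                           .data$metric == object$chosen_metric,
                           .data$sparsity == object$chosen_sparsity),
      size = 3, shape = 1
    ) +
    ggplot2::labs(x = "sparsity", y = "significant channels",
                  title = "Group-difference scan across the sparsity sweep")
}

#' Slice the feature tensor at one (metric, sparsity) choice
#'
#' Extracts the subjects x channels matrix of one nodal metric at one
#' sparsity level — the per-subject feature vector fed to the classifier.
#'
#' @param tensor An `fnirs_tensor`.
#' @param metric One of `"degree"`, `"clustering"`, `"local_efficiency"`,
#'   `"global_efficiency"`.
#' @param sparsity A sparsity level present in the tensor grid.
#' @return A tibble of class `fnirs_features` with columns `subject_id`,
#'   `group`, then one column per channel.
#' @export
select_feature_vector <- function(tensor, metric, sparsity) {
  metric <- match.arg(metric, metric_names())
  levels <- sort(unique(tensor$sparsity))
  hit <- which(abs(levels - sparsity) < 1e-9)
  if (length(hit) != 1) {
    abort(sprintf(
      "Sparsity %.4g not in the tensor grid (levels %s ... %s).",
      sparsity, format(min(levels)), format(max(levels))
    ))
  }
  slice <- dplyr::filter(tensor, .data$metric == !!metric,
                         abs(.data$sparsity - !!sparsity) < 1e-9)
  wide <- tidyr::pivot_wider(
    slice[, c("subject_id", "group", "channel", "value")],
    names_from = "channel", values_from = "value"
  )
  structure(wide, class = c("fnirs_features", class(tibble::tibble())),
            metric = metric, sparsity = levels[hit])
}

#' Feature matrix / labels of an `fnirs_features` slice
#' @param features An `fnirs_features` tibble.
#' @return `features_matrix()`: numeric subjects x channels matrix;
#'   `features_labels()`: integer vector of +1/-1 group labels.
#' @export
features_matrix <- function(features) {
  x <- as.matrix(features[, setdiff(names(features), c("subject_id", "group"))])
  rownames(x) <- features$subject_id
  x
}

#' @rdname features_matrix
#' @export
features_labels <- function(features) as.integer(features$group)
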