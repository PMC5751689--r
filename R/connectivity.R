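#' Pearson correlation matrix of a recording
#'
#' Every channel is a network node; the edge weight between nodes i and j is
#' the Pearson correlation r_ij = cov(X_i, X_j) / (sd(X_i) sd(X_j)) of their
#' time series. The diagonal is exactly 1.
#'
#' @param rec An `fnirs_recording` with N >= 3 samples and no constant
#'   channel.
#' @return A C x C symmetric correlation matrix with channel labels as
#'   dimnames, of class `fnirs_cor`.
#' @export
correlation_matrix <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (n_samples(rec) < 3) abort("Correlation needs at least 3 samples.")
  sds <- apply(rec$data, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance channel(s): %s — correlation undefined.",
                  paste(rec$channel_labels[sds == 0], collapse = ", ")))
  }
  r <- cor(t(rec$data))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  class(r) <- c("fnirs_cor", class(r))
  r
}

#' Map a sparsity level to a correlation threshold
#'
#' Sparsity S is the fraction of realized edges over the maximum possible
#' M = C(C-1)/2. The threshold that achieves sparsity S is the k-th largest
#' absolute off-diagonal correlation, with k = round(S * M) (at S = 0.5 and
#' even M this is the upper median of the ascending |r| values). If rounding
#' gives k = 0 the threshold is `Inf` (empty network).
#'
#' @param corr Correlation matrix (`fnirs_cor` or plain square matrix).
#' @param sparsity Requested sparsity in (0, 1].
#' @param rounding `"round"` (default) or `"floor"` for k = floor(S * M).
#' @return The threshold T (single numeric).
#' @export
sparsity_to_threshold <- function(corr, sparsity, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(sparsity) || length(sparsity) != 1 ||
      sparsity <= 0 || sparsity > 1) {
    abort("`sparsity` must be a single value in (0, 1].")
  }
  vals <- abs(corr[upper.tri(corr)])
  m <- length(vals)
  k <- if (rounding == "round") round(sparsity * m) else floor(sparsity * m)
  if (k < 1) return(Inf)
  sort(vals, decreasing = TRUE)[k]
}

#' Binarize a correlation matrix at a threshold
#'
#' An edge links nodes i and j (i != j) exactly when `|r_ij| >= T`, so
#' strong negative correlations also form edges. The result records the
#' threshold, the achieved sparsity and the edge count; ties at the
#' threshold are always all included, which keeps the construction
#' deterministic (achieved sparsity may then exceed the requested level by
#' the tie-group size over M).
#'
#' @param corr Correlation matrix.
#' @param threshold Nonnegative threshold T on `|r|`.
#' @param sparsity Optional requested sparsity level to record on the result.
#' @return A binary C x C matrix of class `fnirs_adjacency` with attributes
#'   `threshold`, `sparsity` (requested, or NA), `achieved_sparsity` and
#'   `edge_count`.
#' @export
binarize <- function(corr, threshold, sparsity = NA_real_) {
  if (threshold < 0) abort("`threshold` must be nonnegative.")
  e <- (abs(unclass(corr)) >= threshold) * 1L
  diag(e) <- 0L
  storage.mode(e) <- "integer"
  m <- nrow(e) * (nrow(e) - 1) / 2
  edges <- sum(e) / 2
  structure(
    e,
    threshold = threshold,
    sparsity = sparsity,
    achieved_sparsity = if (m > 0) edges / m else 0,
    edge_count = as.integer(edges),
    class = c("fnirs_adjacency", "matrix", "array")
  )
}

#' Maximum number of edges of a C-node network
#' @param n_nodes Node count C.
#' @return C(C-1)/2.
#' @export
max_edges <- function(n_nodes) n_nodes * (n_nodes - 1) / 2

#' The default sparsity grid: 1% to 50% in 1% steps
#' @return Numeric vector of 50 sparsity levels.
#' @export
default_sparsity_grid <- function() round(seq(0.01, 0.50, by = 0.01), 10)

#' Binarize a correlation matrix over a grid of sparsity levels
#'
#' Thresholds the same correlation matrix at each sparsity level of the grid
#' (default 0.01 to 0.50 in steps of 0.01, i.e. 50 networks). Because the
#' threshold is the k-th largest |r|, edge sets are nested along the grid up
#' to tie groups. With `mode = "raw"` the grid values are applied directly as
#' thresholds on |r| instead of as sparsity levels.
#'
#' @param corr Correlation matrix.
#' @param grid Sparsity levels in (0, 1] (or raw thresholds for
#'   `mode = "raw"`).
#' @param mode `"sparsity"` (default) or `"raw"`.
#' @return A tibble with columns `sparsity` (or `threshold` level requested),
#'   `threshold`, `edge_count`, `achieved_sparsity` and a list-column
#'   `adjacency` of `fnirs_adjacency` matrices.
#' @export
threshold_sweep <- function(corr, grid = default_sparsity_grid(),
                            mode = c("sparsity", "raw")) {
  mode <- match.arg(mode)
  if (length(grid) == 0) abort("Sparsity grid must be non-empty.")
  if (mode == "sparsity" && any(grid <= 0 | grid > 1)) {
    abort("Sparsity levels must lie in (0, 1].")
  }
  adj <- lapply(grid, function(s) {
    thr <- if (mode == "sparsity") sparsity_to_threshold(corr, s) else s
    binarize(corr, thr, sparsity = if (mode == "sparsity") s else NA_real_)
  })
  tibble::tibble(
    level = grid,
    threshold = vapply(adj, attr, numeric(1), "threshold"),
    edge_count = vapply(adj, attr, integer(1), "edge_count"),
    achieved_sparsity = vapply(adj, attr, numeric(1), "achieved_sparsity"),
    adjacency = adj
  )
}

#' @method autoplot fnirs_cor
#' @export
autoplot.fnirs_cor <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = ~ c("from", "to", "r"))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, title = "Channel correlation matrix")
}
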