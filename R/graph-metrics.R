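#' Nodal metrics of a binary undirected network
#'
#' Four per-node attributes summarise a binarized functional network:
#'
#' * **degree** — number of incident edges, k_i.
#' * **clustering coefficient** (Watts–Strogatz) — fraction of a node's
#'   neighbour pairs that are themselves connected, 2 t_i / (k_i (k_i - 1));
#'   0 when k_i < 2.
#' * **nodal global efficiency** (Latora–Marchiori) — mean inverse shortest
#'   path length from the node to all others, with 1/Inf = 0 for unreachable
#'   pairs.
#' * **nodal local efficiency** — global efficiency of the subgraph induced
#'   by the node's neighbours; 0 when k_i < 2.
#'
#' Distances are unweighted hop counts on the binary network; disconnected
#' components are kept (no largest-component restriction), so all metrics
#' stay defined at sparse thresholds.
#'
#' @param adj An `fnirs_adjacency` matrix (or any symmetric binary matrix
#'   with zero diagonal).
#' @return `metric_profile()`: a tibble with columns `channel`, `sparsity`,
#'   `degree`, `clustering`, `local_efficiency`, `global_efficiency`. The
#'   individual metric functions return plain numeric vectors of length C.
#' @name graph_metrics
NULL

as_adj_matrix <- function(adj) {
  m <- unclass(adj)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

adj_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(as_adj_matrix(adj), mode = "undirected",
                                      diag = FALSE)
}

#' @rdname graph_metrics
#' @export
nodal_degree <- function(adj) {
  as.integer(rowSums(as_adj_matrix(adj)))
}

# Unweighted all-pairs hop distances by breadth-first level expansion:
# walk counts adj^s are positive exactly when a length-s walk exists, and the
# first such s is the shortest-path length. O(diameter) matrix products.
matrix_distances <- function(m) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  if (n == 0) return(d)
  diag(d) <- 0
  adj <- (m != 0) * 1
  cur <- adj
  step <- 1
  repeat {
    upd <- (cur > 0) & is.infinite(d)
    if (!any(upd)) break
    d[upd] <- step
    if (step >= n) break
    cur <- cur %*% adj
    step <- step + 1
  }
  d
}

#' @rdname graph_metrics
#' @export
shortest_paths_matrix <- function(adj) {
  m <- as_adj_matrix(adj)
  d <- matrix_distances(m)
  dimnames(d) <- dimnames(m)
  d
}

#' @rdname graph_metrics
#' @export
clustering_coefficient <- function(adj) {
  g <- adj_graph(adj)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  as.numeric(cc)
}

#' @rdname graph_metrics
#' @export
nodal_global_efficiency <- function(adj) {
  d <- shortest_paths_matrix(adj)
  c_nodes <- nrow(d)
  if (c_nodes < 2) return(rep(0, c_nodes))
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (c_nodes - 1)
}

#' @rdname graph_metrics
#' @export
nodal_local_efficiency <- function(adj) {
  m <- as_adj_matrix(adj)
  vapply(seq_len(nrow(m)), function(i) {
    nb <- which(m[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    d <- matrix_distances(m[nb, nb, drop = FALSE])
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

#' Network-level global efficiency
#'
#' The scalar companion of [nodal_global_efficiency()]: the mean over all
#' ordered node pairs of the inverse shortest path length.
#'
#' @param adj An `fnirs_adjacency` matrix.
#' @return A single number in \[0, 1\].
#' @export
global_efficiency <- function(adj) {
  e <- nodal_global_efficiency(adj)
  if (length(e) == 0) return(0)
  mean(e)
}

#' @rdname graph_metrics
#' @export
metric_profile <- function(adj) {
  labels <- rownames(as_adj_matrix(adj)) %||%
    sprintf("CH%02d", seq_len(nrow(adj)))
  tibble::tibble(
    channel = labels,
    sparsity = attr(adj, "sparsity") %||% NA_real_,
    degree = nodal_degree(adj),
    clustering = clustering_coefficient(adj),
    local_efficiency = nodal_local_efficiency(adj),
    global_efficiency = nodal_global_efficiency(adj)
  )
}

metric_names <- function() {
  c("degree", "clustering", "local_efficiency", "global_efficiency")
}
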