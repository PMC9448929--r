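#' Connection-length transform
#'
#' Converts edge weights to connection lengths `1/w` (the standard transform
#' for streamline-weight connectomes): strong edges are short, absent edges
#' have infinite length. Diagonal is 0.
#'
#' @param W symmetric nonnegative weight matrix.
#' @return Length matrix with `Inf` where `W == 0` off the diagonal.
#' @export
to_lengths <- function(W) {
  stopifnot(is.matrix(W), all(W >= 0))
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  L
}

# igraph on the positive edges, weighted by length
lengths_to_graph <- function(lengths) {
  A <- ifelse(is.finite(lengths), lengths, 0)
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
}

#' All-pairs shortest-path distances
#'
#' Dijkstra distances on the connection-length graph. Unreachable pairs get
#' `Inf`.
#'
#' @param lengths length matrix from [to_lengths()].
#' @return Symmetric distance matrix `d` with zero diagonal.
#' @export
shortest_paths_matrix <- function(lengths) {
  g <- lengths_to_graph(lengths)
  d <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Global efficiency
#'
#' `GE = (1/n) sum_j [ sum_{h != j} 1/d_jh ] / (n - 1)`; unreachable pairs
#' contribute 0 (harmonic convention), so GE stays defined under severe
#' lesioning.
#'
#' @param d distance matrix from [shortest_paths_matrix()].
#' @return Scalar efficiency, >= 0.
#' @export
global_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("degenerate input: need at least 2 nodes")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic (mean shortest) path length
#'
#' Mean of `d_jh` over ordered pairs `j != h`, restricted to reachable
#' pairs; the number of unreachable ordered pairs is reported alongside.
#'
#' @param d distance matrix.
#' @return List with `L` (NA if no pair is reachable, with a warning) and
#'   `n_unreachable_pairs`.
#' @export
char_path_length <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("degenerate input: need at least 2 nodes")
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  if (!any(reach)) {
    warning("no reachable pairs; characteristic path length undefined")
    return(list(L = NA_real_, n_unreachable_pairs = sum(!reach)))
  }
  list(L = mean(off[reach]), n_unreachable_pairs = sum(!reach))
}

#' Betweenness centrality
#'
#' `BC_j = [1/((n-1)(n-2))] sum_{g != h != j} rho_gh(j)/rho_gh`, with
#' shortest paths on the connection-length graph and the sum over ordered
#' pairs, so values lie in `[0, 1]`.
#'
#' @param lengths length matrix from [to_lengths()].
#' @return Numeric vector of per-node centralities.
#' @export
betweenness_centrality <- function(lengths) {
  n <- nrow(lengths)
  if (n < 3) stop("degenerate input: need at least 3 nodes")
  g <- lengths_to_graph(lengths)
  b <- igraph::betweenness(g, weights = igraph::E(g)$weight, directed = FALSE)
  # igraph counts unordered pairs; the ordered-pair sum is twice that
  as.numeric(2 * b / ((n - 1) * (n - 2)))
}

#' Clustering coefficients
#'
#' Binary mode (default) follows `CC_j = 2 t_j / (k_j (k_j - 1))` on the
#' binarized (`W > 0`) graph, with `t_j` the triangle count and `k_j` the
#' binary degree; nodes with `k_j < 2` get 0. Weighted mode uses the
#' geometric-mean triangle intensity of the weights (normalized by the
#' maximum weight) over the same binary degree.
#'
#' @param W symmetric nonnegative weight matrix.
#' @param mode `"binary"` or `"weighted"`.
#' @return Numeric vector of per-node clustering coefficients in `[0, 1]`.
#' @export
clustering_coefficients <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(W), all(W >= 0))
  A <- (W > 0) * 1
  diag(A) <- 0
  k <- rowSums(A)
  denom <- k * (k - 1)
  if (mode == "binary") {
    t2 <- diag(A %*% A %*% A)      # 2 * t_j
  } else {
    Wh <- (W / max(W))^(1 / 3)
    diag(Wh) <- 0
    t2 <- diag(Wh %*% Wh %*% Wh)
  }
  cc <- ifelse(denom > 0, t2 / denom, 0)
  as.numeric(cc)
}

#' Graph-metric record for one subject
#'
#' Computes the full weighted-graph profile of one SC matrix: global
#' efficiency, mean shortest path length, mean betweenness centrality and
#' mean clustering coefficient.
#'
#' @param cm a [connectome] (or bare weight matrix).
#' @param cc_mode clustering mode, see [clustering_coefficients()].
#' @return One-row data.frame: subject_id, GE, MSPL, mean_BC, mean_CC,
#'   n_unreachable_pairs.
#' @export
graph_metrics <- function(cm, cc_mode = "binary") {
  W <- if (inherits(cm, "connectome")) cm$W else cm
  sid <- if (inherits(cm, "connectome")) cm$subject_id else "matrix"
  lengths <- to_lengths(W)
  d <- shortest_paths_matrix(lengths)
  cpl <- char_path_length(d)
  data.frame(subject_id = sid,
             GE = global_efficiency(d),
             MSPL = cpl$L,
             mean_BC = mean(betweenness_centrality(lengths)),
             mean_CC = mean(clustering_coefficients(W, mode = cc_mode)),
             n_unreachable_pairs = cpl$n_unreachable_pairs)
}

#' Graph metrics for a population
#' @param population list of [connectome] objects.
#' @param ... passed to [graph_metrics()].
#' @return Data frame with one row per subject.
#' @export
population_metrics <- function(population, ...) {
  do.call(rbind, lapply(population, graph_metrics, ...))
}
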