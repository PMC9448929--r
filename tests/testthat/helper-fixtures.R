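# shared fixtures and independent brute-force oracles

map_to_reference_test <- connectotype:::map_to_reference
canonical_q <- connectotype:::canonical_labels

# random symmetric nonnegative matrix with zero diagonal
random_sc <- function(n, density = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  vals <- runif(sum(ut), 0.1, 5)
  vals[runif(sum(ut)) > density] <- 0
  W[ut] <- vals
  W + t(W)
}

tiny_parcellation <- function(n, k = 2) {
  parcellation("tiny", rep(paste0("S", seq_len(k)), each = ceiling(n / k))[1:n])
}

uniform_parcellation <- function(n) {
  parcellation("uniformN", paste0("S", seq_len(n)))
}

as_connectome <- function(W, ...) {
  connectome(W, uniform_parcellation(nrow(W)), ...)
}

write_matrix_file <- function(W, path = tempfile(fileext = ".tsv")) {
  write.table(W, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# ---- graph oracles (exhaustive, n <= 8) -----------------------------------

# all simple paths between a and b as lists of node sequences
all_simple_paths_nodes <- function(adj, a, b) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(node, visited, path) {
    if (node == b) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (nb in which(adj[node, ] > 0)) {
      if (!visited[nb]) {
        v <- visited; v[nb] <- TRUE
        walk(nb, v, c(path, nb))
      }
    }
  }
  visited <- rep(FALSE, n); visited[a] <- TRUE
  walk(a, visited, a)
  paths
}

path_length <- function(lengths, path) {
  if (length(path) < 2) return(0)
  sum(lengths[cbind(path[-length(path)], path[-1])])
}

# exhaustive all-pairs shortest distances on a length matrix
oracle_shortest_paths <- function(lengths) {
  n <- nrow(lengths)
  adj <- is.finite(lengths) & lengths > 0
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    ps <- all_simple_paths_nodes(adj, a, b)
    if (length(ps))
      d[a, b] <- d[b, a] <- min(vapply(ps, path_length, numeric(1),
                                       lengths = lengths))
  }
  d
}

# exhaustive betweenness (ordered-pair normalization, values in [0, 1])
oracle_betweenness <- function(lengths) {
  n <- nrow(lengths)
  adj <- is.finite(lengths) & lengths > 0
  bc <- numeric(n)
  for (g in 1:n) for (h in 1:n) {
    if (g == h) next
    ps <- all_simple_paths_nodes(adj, g, h)
    if (!length(ps)) next
    lens <- vapply(ps, path_length, numeric(1), lengths = lengths)
    short <- ps[abs(lens - min(lens)) < 1e-12]
    for (j in setdiff(1:n, c(g, h))) {
      through <- vapply(short, function(p) j %in% p, logical(1))
      bc[j] <- bc[j] + mean(through)
    }
  }
  bc / ((n - 1) * (n - 2))
}

# direct triple-enumeration clustering coefficient on the binarized graph
oracle_clustering <- function(W) {
  A <- (W > 0) * 1; diag(A) <- 0
  n <- nrow(A)
  vapply(1:n, function(j) {
    nb <- which(A[j, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    t_j <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] > 0) t_j <- t_j + 1
    }
    2 * t_j / (k * (k - 1))
  }, numeric(1))
}

# ---- modularity oracle (exhaustive over set partitions, m <= 8) -----------

all_set_partitions <- function(m) {
  if (m == 1) return(list(c(1L)))
  smaller <- all_set_partitions(m - 1)
  out <- list()
  for (p in smaller) {
    for (g in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

oracle_best_partition <- function(sim, gamma) {
  parts <- all_set_partitions(length(sim$subject_ids))
  qs <- vapply(parts, function(p) modularity_Q(sim, p, gamma), numeric(1))
  list(Q = max(qs), partition = parts[[which.max(qs)]])
}

# similarity matrix object from a raw matrix
sim_from_matrix <- function(S, ids = sprintf("s%02d", seq_len(nrow(S)))) {
  structure(list(subject_ids = ids, S = S), class = "similarity_matrix")
}

# two-block similarity fixture
two_block_sim <- function(m1, m2, within = 0.9, between = 0.1, noise = 0,
                          seed = 1) {
  set.seed(seed)
  m <- m1 + m2
  S <- matrix(between, m, m)
  S[1:m1, 1:m1] <- within
  S[(m1 + 1):m, (m1 + 1):m] <- within
  if (noise > 0) {
    E <- matrix(rnorm(m * m, sd = noise), m, m)
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  sim_from_matrix(S)
}
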