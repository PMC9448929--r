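#' Subject-similarity matrix from edge vectors
#'
#' Pearson correlation of every pair of subjects' edge vectors; 1 is perfect
#' similarity, -1 anticorrelation. Diagonal is set to exactly 1.
#'
#' @param vectors list of `edge_vector`s (see [vectorize_edges()]), all of
#'   the same subset and length >= 3.
#' @return A `similarity_matrix`: list with `subject_ids` and matrix `S`.
#' @export
similarity_matrix <- function(vectors) {
  stopifnot(length(vectors) >= 2)
  ids <- vapply(vectors, `[[`, character(1), "subject_id")
  lens <- vapply(vectors, function(v) length(v$values), integer(1))
  if (length(unique(lens)) != 1L || lens[1L] < 3L)
    stop("all edge vectors must share one length >= 3")
  V <- vapply(vectors, `[[`, numeric(lens[1L]), "values")
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("validation error: zero-variance edge vector for subject(s) %s",
                 paste(ids[sds == 0], collapse = ", ")))
  S <- stats::cor(V)
  diag(S) <- 1
  dimnames(S) <- NULL
  structure(list(subject_ids = ids, S = S), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$S[upper.tri(x$S)]
  cat(sprintf("<similarity_matrix> %d subjects, mean r = %.3f (range %.3f..%.3f)\n",
              length(x$subject_ids), mean(off), min(off), max(off)))
  invisible(x)
}

# similarity prepared for modularity: negative-weight policy applied. The
# unit self-similarity diagonal is retained (the similarity matrix is used
# as-is, as in toolbox community detection on correlation matrices); at
# small sample sizes dropping it would bias Q against any split by one
# null-term per subject.
modularity_weights <- function(sim, negative_policy = c("zero", "asymmetric")) {
  negative_policy <- match.arg(negative_policy)
  A <- sim$S
  if (negative_policy == "zero") A[A < 0] <- 0
  A
}

#' Modularity of a subject partition
#'
#' `Q(gamma) = (1/2m) sum_jh [A_jh - gamma P_jh] delta(sigma_j, sigma_h)`
#' with the configuration null `P_jh = s_j s_h / (2m)` (`s` = similarity row
#' sums, `2m` = total weight). Normalization by `2m` follows the standard
#' convention; it rescales Q without changing which partition is optimal.
#'
#' @param sim a [similarity_matrix()].
#' @param assignment module label per subject (any label type).
#' @param gamma resolution parameter (> 0).
#' @param negative_policy how to treat negative similarities before
#'   modularity: `"zero"` (default) clips them to 0.
#' @return Scalar modularity Q.
#' @export
modularity_Q <- function(sim, assignment, gamma = 1,
                         negative_policy = "zero") {
  stopifnot(inherits(sim, "similarity_matrix"),
            length(assignment) == length(sim$subject_ids), gamma > 0)
  A <- modularity_weights(sim, negative_policy)
  two_m <- sum(A)
  if (two_m == 0) return(0)
  s <- rowSums(A)
  same <- outer(assignment, assignment, `==`)
  sum((A - gamma * outer(s, s) / two_m)[same]) / two_m
}

#' Maximize modularity over subject partitions
#'
#' Greedy multi-level (Louvain-style) optimization of `Q(gamma)`, run from
#' `n_restarts` random node orders; deterministic given `seed`. The best-Q
#' partition is kept, ties broken toward fewer modules and then the
#' lexicographically smallest canonical assignment.
#'
#' @param sim a [similarity_matrix()].
#' @param gamma resolution (> 0).
#' @param n_restarts random restarts (>= 1).
#' @param seed integer seed for the restart orders.
#' @param negative_policy see [modularity_Q()].
#' @return A `module_partition`: list with `assignment` (integer module per
#'   subject, labelled 1..k in order of first appearance), `subject_ids`,
#'   `Q`, `gamma`, `n_modules`.
#' @export
maximize_modularity <- function(sim, gamma = 1, n_restarts = 100L, seed = 1L,
                                negative_policy = "zero") {
  stopifnot(inherits(sim, "similarity_matrix"), gamma > 0, n_restarts >= 1)
  A <- modularity_weights(sim, negative_policy)
  m <- nrow(A)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ord <- with_seed(derive_seed(seed, r, salt = 13L), sample.int(m))
    memb <- canonical_labels(louvain_membership(A, gamma, ord))
    Q <- modularity_Q(sim, memb, gamma, negative_policy)
    cand <- list(assignment = memb, Q = Q, n_modules = length(unique(memb)))
    if (is.null(best) || Q > best$Q + 1e-12 ||
        (Q > best$Q - 1e-12 &&
         (cand$n_modules < best$n_modules ||
          (cand$n_modules == best$n_modules &&
           lexicographically_smaller(memb, best$assignment))))) {
      best <- cand
    }
  }
  if (best$Q <= 1e-12 || best$n_modules == m) {
    # nothing beats the configuration null (or only self-similarity does,
    # leaving every subject alone): the sample cannot be organized
    one <- rep(1L, m)
    best <- list(assignment = one,
                 Q = modularity_Q(sim, one, gamma, negative_policy),
                 n_modules = 1L)
  }
  structure(list(assignment = best$assignment,
                 subject_ids = sim$subject_ids,
                 Q = best$Q, gamma = gamma, n_modules = best$n_modules),
            class = "module_partition")
}

lexicographically_smaller <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1L]] < b[d[1L]]
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d subjects -> %d module(s), gamma = %g, Q = %.4f\n",
              length(x$assignment), x$n_modules, x$gamma, x$Q))
  print(table(module = x$assignment))
  invisible(x)
}

#' Find the minimum resolution producing two nontrivial modules
#'
#' Scans an ascending gamma grid and returns the smallest value whose
#' optimal partition has exactly two modules, each holding at least
#' `min_frac` of the subjects.
#'
#' @param sim a [similarity_matrix()].
#' @param gamma_grid ascending resolutions (default 0.5 to 1.5 by 0.01).
#' @param min_frac minimum module size as a fraction of subjects.
#' @param n_restarts,seed,negative_policy see [maximize_modularity()].
#' @return List with `gamma` and the corresponding `partition`.
#' @export
find_min_gamma <- function(sim, gamma_grid = seq(0.5, 1.5, by = 0.01),
                           min_frac = 0.05, n_restarts = 100L, seed = 1L,
                           negative_policy = "zero") {
  stopifnot(length(gamma_grid) >= 1, all(diff(gamma_grid) > 0))
  m <- length(sim$subject_ids)
  for (g in gamma_grid) {
    part <- maximize_modularity(sim, gamma = g, n_restarts = n_restarts,
                                seed = seed, negative_policy = negative_policy)
    if (part$n_modules == 2L &&
        min(table(part$assignment)) >= min_frac * m)
      return(list(gamma = g, partition = part))
    if (part$n_modules > 2L) break  # past the two-module regime
  }
  stop("search failure: no gamma in the grid produced two nontrivial modules; widen the grid")
}

#' k-fold cross-validation of module assignments
#'
#' For each fold, the two-module partition is re-derived on the retained
#' subjects (re-running the minimum-gamma search), its modules are mapped to
#' the reference modules by maximal overlap, and each withheld subject is
#' assigned to the module whose members have the highest mean similarity to
#' it. Accuracy is the fraction of withheld subjects landing in their
#' whole-sample module, averaged over folds.
#'
#' @param sim a [similarity_matrix()].
#' @param reference a `module_partition` on the full sample.
#' @param k number of folds (subjects must number at least `2k`).
#' @param seed integer seed for the fold split and restarts.
#' @param gamma_grid,min_frac,n_restarts passed to [find_min_gamma()].
#' @return List with `accuracy` (mean over folds), `fold_accuracy`, and
#'   `failed_folds` (folds whose gamma search failed, skipped).
#' @export
crossval_accuracy <- function(sim, reference, k = 5L, seed = 1L,
                              gamma_grid = seq(0.5, 1.5, by = 0.01),
                              min_frac = 0.05, n_restarts = 100L) {
  m <- length(sim$subject_ids)
  stopifnot(inherits(reference, "module_partition"), m >= 2 * k)
  folds <- with_seed(derive_seed(seed, 1L, salt = 23L),
                     sample(rep(seq_len(k), length.out = m)))
  fold_acc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    sub <- structure(list(subject_ids = sim$subject_ids[train],
                          S = sim$S[train, train]),
                     class = "similarity_matrix")
    res <- tryCatch(
      find_min_gamma(sub, gamma_grid = gamma_grid, min_frac = min_frac,
                     n_restarts = n_restarts,
                     seed = derive_seed(seed, f, salt = 29L)),
      error = function(e) NULL)
    if (is.null(res)) next
    mapped <- map_to_reference(res$partition$assignment,
                               reference$assignment[train])
    correct <- vapply(test, function(i) {
      mean_sim <- vapply(unique(mapped), function(mod)
        mean(sim$S[i, train[mapped == mod]]), numeric(1))
      predicted <- unique(mapped)[which.max(mean_sim)]
      predicted == reference$assignment[i]
    }, logical(1))
    fold_acc[f] <- mean(correct)
  }
  list(accuracy = mean(fold_acc, na.rm = TRUE),
       fold_accuracy = fold_acc,
       failed_folds = which(is.na(fold_acc)))
}

#' Module agreement when clustering on an edge subset
#'
#' Rebuilds the similarity matrix from only the fine edges in `subset`,
#' re-runs the minimum-gamma two-module search, maps the subset modules onto
#' the reference modules by maximal overlap, and reports the fraction of
#' subjects keeping their reference module. A failed gamma search is a
#' status, not an error.
#'
#' @param population list of [connectome] objects (fine parcellation), in
#'   the same order as the reference partition's subjects.
#' @param subset an [edge_subset()].
#' @param reference a two-module `module_partition` on the same subjects.
#' @param gamma_grid,min_frac,n_restarts,seed passed to [find_min_gamma()].
#' @return List with `status` (`"ok"` or `"failed-to-produce-two-modules"`),
#'   `accuracy` (NA on failure), `partition`, and the subset `similarity`.
#' @export
subset_accuracy <- function(population, subset, reference,
                            gamma_grid = seq(0.5, 1.5, by = 0.01),
                            min_frac = 0.05, n_restarts = 100L, seed = 1L) {
  stopifnot(inherits(reference, "module_partition"),
            reference$n_modules == 2L,
            length(population) == length(reference$assignment))
  vecs <- lapply(population, vectorize_edges, subset = subset)
  sim <- similarity_matrix(vecs)
  res <- tryCatch(
    find_min_gamma(sim, gamma_grid = gamma_grid, min_frac = min_frac,
                   n_restarts = n_restarts, seed = seed),
    error = function(e) NULL)
  if (is.null(res))
    return(list(status = "failed-to-produce-two-modules", accuracy = NA_real_,
                partition = NULL, similarity = sim))
  mapped <- map_to_reference(res$partition$assignment, reference$assignment)
  list(status = "ok",
       accuracy = mean(mapped == reference$assignment),
       partition = res$partition, similarity = sim)
}

#' Representative (mean) matrix per module
#'
#' Entrywise mean of the member subjects' matrices for each module, at the
#' fine or system (coarse) level.
#'
#' @param population list of [connectome] objects matching the partition.
#' @param partition a `module_partition`.
#' @param level `"fine"` (native matrices) or `"coarse"` (reparcellated).
#' @return Named list of mean weight matrices, one per module.
#' @export
representative_matrix <- function(population, partition,
                                  level = c("fine", "coarse")) {
  level <- match.arg(level)
  stopifnot(length(population) == length(partition$assignment))
  mats <- lapply(population, function(cm) {
    if (level == "coarse") reparcellate(cm)$W else cm$W
  })
  mods <- sort(unique(partition$assignment))
  out <- lapply(mods, function(mod) {
    members <- which(partition$assignment == mod)
    if (length(members) == 0L) stop("validation error: empty module")
    Reduce(`+`, mats[members]) / length(members)
  })
  names(out) <- paste0("module", mods)
  out
}

#' Cluster a population into architecture types
#'
#' Convenience wrapper for the whole-network pipeline stage: reparcellate
#' each subject to the system level, vectorize the between-system edges,
#' build the similarity matrix and run the minimum-gamma two-module search.
#'
#' @param population list of [connectome] objects.
#' @param gamma_grid,min_frac,n_restarts,seed see [find_min_gamma()].
#' @return List with `similarity`, `gamma`, `partition`.
#' @export
cluster_population <- function(population,
                               gamma_grid = seq(0.5, 1.5, by = 0.01),
                               min_frac = 0.05, n_restarts = 100L,
                               seed = 1L) {
  vecs <- lapply(population, function(cm) vectorize_edges(reparcellate(cm)))
  sim <- similarity_matrix(vecs)
  res <- find_min_gamma(sim, gamma_grid = gamma_grid, min_frac = min_frac,
                        n_restarts = n_restarts, seed = seed)
  list(similarity = sim, gamma = res$gamma, partition = res$partition)
}
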