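#' Population-consistent hub ranking
#'
#' Ranks nodes by connectivity within each subject (rank 1 = most connected,
#' ties to the lower node index), averages the rank positions across
#' subjects, and orders nodes by ascending mean rank (descending population
#' connectivity). Using one shared ranking guarantees the same nodes are
#' severed in every subject.
#'
#' @param population list of [connectome] objects on one parcellation.
#' @param measure `"strength"` (weighted degree, default; weighted SC is
#'   near-fully dense so binary degree is uninformative) or
#'   `"binary_degree"`.
#' @param levels cumulative lesion fractions (ascending, in (0, 1]).
#' @return A `lesion_plan`: list with `ranked_nodes` (permutation of node
#'   indices, most connected first), `mean_rank`, `levels`, `measure`.
#' @export
rank_nodes <- function(population, measure = c("strength", "binary_degree"),
                       levels = c(0.05, 0.10, 0.25, 0.50, 0.75)) {
  measure <- match.arg(measure)
  stopifnot(length(population) >= 1, all(levels > 0), all(levels <= 1),
            all(diff(levels) > 0))
  parcs <- unique(vapply(population, function(cm) cm$parcellation$name,
                         character(1)))
  ns <- unique(vapply(population, function(cm) nrow(cm$W), integer(1)))
  if (length(parcs) != 1L || length(ns) != 1L)
    stop("validation error: subjects must share one parcellation")
  n <- ns
  ranks <- vapply(population, function(cm) {
    deg <- if (measure == "strength") rowSums(cm$W) else rowSums(cm$W > 0)
    ord <- order(-deg, seq_len(n))        # rank 1 = highest, ties by index
    rank_pos <- integer(n)
    rank_pos[ord] <- seq_len(n)
    rank_pos
  }, integer(n))
  mean_rank <- rowMeans(ranks)
  structure(list(ranked_nodes = order(mean_rank, seq_len(n)),
                 mean_rank = mean_rank, levels = levels, measure = measure),
            class = "lesion_plan")
}

#' @export
print.lesion_plan <- function(x, ...) {
  cat(sprintf("<lesion_plan> %d nodes ranked by %s; levels: %s; top 5: %s\n",
              length(x$ranked_nodes), x$measure,
              paste(x$levels, collapse = ", "),
              paste(utils::head(x$ranked_nodes, 5), collapse = ", ")))
  invisible(x)
}

#' Nodes severed at a lesion level
#' @param plan a `lesion_plan`.
#' @param level fraction in (0, 1]; the top `ceiling(level * n)` ranked
#'   nodes are severed, so levels are cumulative (higher levels strictly
#'   contain lower ones).
#' @return Integer vector of lesioned node indices.
#' @export
lesioned_nodes <- function(plan, level) {
  stopifnot(inherits(plan, "lesion_plan"), level > 0, level <= 1)
  n <- length(plan$ranked_nodes)
  plan$ranked_nodes[seq_len(ceiling(level * n))]
}

#' Apply a cumulative hub lesion
#'
#' Zeroes the rows and columns of the top-ranked nodes. Lesioned nodes stay
#' in the matrix as disconnected oscillators, keeping N constant for the
#' order parameter; use `drop_nodes = TRUE` to delete them instead.
#'
#' @param cm a [connectome].
#' @param plan a `lesion_plan` built on the same parcellation.
#' @param level lesion fraction in (0, 1].
#' @param drop_nodes if `TRUE`, remove the lesioned rows/columns entirely
#'   (the returned matrix loses its parcellation binding).
#' @return A [connectome] (or bare matrix when `drop_nodes = TRUE`).
#' @export
apply_lesion <- function(cm, plan, level, drop_nodes = FALSE) {
  stopifnot(inherits(cm, "connectome"))
  cut <- lesioned_nodes(plan, level)
  W <- cm$W
  W[cut, ] <- 0
  W[, cut] <- 0
  if (drop_nodes) return(W[-cut, -cut, drop = FALSE])
  cm$W <- W
  cm
}

#' Lesion experiment over a population
#'
#' For every subject and lesion level (level 0 = intact), computes the graph
#' metrics of the lesioned matrix and, optionally, the Kuramoto coupling
#' sweep. The coupling matrix is normalized once on the intact network and
#' then lesioned, so a lesion reduces total coupling rather than being
#' silently renormalized away (`renormalize = TRUE` restores per-level
#' normalization).
#'
#' @param population list of [connectome] objects.
#' @param plan a `lesion_plan`; its `levels` are used unless `levels` is
#'   given.
#' @param levels lesion fractions; 0 is always prepended.
#' @param km_settings `NULL` to skip dynamics, or a list of arguments for
#'   [coupling_sweep()] (e.g. `list(K_grid = seq(0, 2, 0.1), T = 20)`).
#' @param renormalize re-normalize the coupling matrix after each lesion.
#' @param seed master seed for the sweeps.
#' @param cc_mode clustering mode for [graph_metrics()].
#' @return Long-format data.frame keyed by (subject_id, level) with the
#'   metric columns and, when dynamics are run, Kcrit_syn, Kcrit_mts,
#'   auc_synchrony and a `sweeps` attribute (list indexed by subject/level).
#' @export
lesion_experiment <- function(population, plan, levels = plan$levels,
                              km_settings = NULL, renormalize = FALSE,
                              seed = 1L, cc_mode = "binary") {
  stopifnot(inherits(plan, "lesion_plan"))
  levels <- sort(unique(c(0, levels)))
  rows <- list()
  sweeps <- list()
  for (i in seq_along(population)) {
    cm <- population[[i]]
    C0 <- if (!is.null(km_settings)) normalize_for_km(cm) else NULL
    for (lev in levels) {
      lcm <- if (lev == 0) cm else apply_lesion(cm, plan, lev)
      row <- cbind(graph_metrics(lcm, cc_mode = cc_mode), level = lev)
      if (!is.null(km_settings)) {
        C <- C0
        if (lev > 0) {
          cut <- lesioned_nodes(plan, lev)
          C[cut, ] <- 0
          C[, cut] <- 0
          if (renormalize && sum(C) > 0) {
            n <- nrow(C)
            C <- C / (sum(C) / (n * (n - 1)))
          }
        }
        sw <- do.call(coupling_sweep,
                      c(list(cm = lcm, C = C,
                             seed = derive_seed(seed, i, salt = 31L)),
                        km_settings))
        row$Kcrit_syn <- sw$Kcrit_syn
        row$Kcrit_mts <- sw$Kcrit_mts
        row$auc_synchrony <- sw$auc_synchrony
        row$max_synchrony <- max(sw$synchrony)
        sweeps[[paste0(cm$subject_id, "@", lev)]] <- sw
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(sweeps)) attr(out, "sweeps") <- sweeps
  out
}
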