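#' One-way ANOVA across labelled groups
#'
#' @param samples named list mapping group label to a numeric vector
#'   (>= 2 groups, each with >= 2 values).
#' @return List with the F statistic and its p-value.
#' @export
one_way_anova <- function(samples) {
  check_samples(samples)
  df <- samples_to_df(samples)
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1L]]
  list(F = s[["F value"]][1L], p = s[["Pr(>F)"]][1L])
}

check_samples <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L || is.null(names(samples)))
    stop("validation error: need a named list of >= 2 groups")
  sizes <- lengths(samples)
  if (any(sizes < 2L))
    stop(sprintf("validation error: group(s) %s have < 2 values",
                 paste(names(samples)[sizes < 2L], collapse = ", ")))
  invisible(TRUE)
}

samples_to_df <- function(samples) {
  data.frame(
    value = unlist(samples, use.names = FALSE),
    group = factor(rep(names(samples), lengths(samples)),
                   levels = names(samples)))
}

#' Tukey-Kramer pairwise comparisons and pairing classes
#'
#' All pairwise group contrasts with the studentized-range (Tukey HSD)
#' correction, valid for unequal group sizes (Tukey-Kramer). Pairing classes
#' are the connected components of the "not significantly different at
#' alpha" graph (transitive closure), reproducing the shared-color tables of
#' group-comparison summaries.
#'
#' @param samples named list of numeric vectors per group.
#' @param alpha significance level for the pairing classes.
#' @return List with `pairwise` (data.frame: group1, group2, diff,
#'   p_adjusted) and `pairing_classes` (list of character vectors covering
#'   all groups).
#' @export
tukey_kramer <- function(samples, alpha = 0.05) {
  check_samples(samples)
  df <- samples_to_df(samples)
  hsd <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
  pairs <- do.call(rbind, strsplit(rownames(hsd), "-", fixed = TRUE))
  pairwise <- data.frame(group1 = pairs[, 2L], group2 = pairs[, 1L],
                         diff = hsd[, "diff"],
                         p_adjusted = hsd[, "p adj"],
                         row.names = NULL)
  groups <- names(samples)
  adj <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  diag(adj) <- TRUE
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$p_adjusted[i] >= alpha) {
      adj[pairwise$group1[i], pairwise$group2[i]] <- TRUE
      adj[pairwise$group2[i], pairwise$group1[i]] <- TRUE
    }
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  classes <- split(groups, comp$membership)
  names(classes) <- NULL
  list(pairwise = pairwise, pairing_classes = classes)
}

#' Trapezoidal area under a curve
#'
#' @param x strictly ascending abscissae (length >= 2).
#' @param y curve values.
#' @return Scalar trapezoidal area.
#' @export
curve_auc <- function(x, y) trapezoid(x, y)

#' Group comparison for one metric
#'
#' @param values numeric vector of per-subject values.
#' @param groups group label per subject.
#' @param alpha significance level.
#' @return A `group_comparison`: list with `F`, `p`, `pairwise`,
#'   `pairing_classes`, and a normality screen (R-squared of the
#'   quantile-quantile line per group, logged, not enforced).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  samples <- split(values, groups)
  an <- one_way_anova(samples)
  tk <- tukey_kramer(samples, alpha = alpha)
  qq_r2 <- vapply(samples, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    q <- stats::qnorm(stats::ppoints(length(v)))
    stats::cor(sort(v), q)^2
  }, numeric(1))
  structure(list(F = an$F, p = an$p, pairwise = tk$pairwise,
                 pairing_classes = tk$pairing_classes, alpha = alpha,
                 qq_linearity_r2 = qq_r2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F = %.3f, p = %.3g; classes: %s\n",
              x$F, x$p,
              paste(vapply(x$pairing_classes, paste, character(1),
                           collapse = "+"), collapse = " | ")))
  invisible(x)
}

#' Assemble the per-module statistical report
#'
#' Runs a [compare_groups()] comparison for every metric column, using the
#' module assignment (crossed with sex labels when given) as the categorical
#' factor.
#'
#' @param partition a `module_partition`.
#' @param metrics data.frame keyed by subject_id with metric columns (e.g.
#'   the output of [population_metrics()], [population_sweeps()], or a
#'   single level of [lesion_experiment()]).
#' @param metric_cols columns of `metrics` to compare (default: all numeric
#'   columns except the key).
#' @param sex optional sex label per partition subject; groups become
#'   sex-module combinations (the M1/M2/F1/F2 labelling).
#' @param alpha significance level.
#' @return Named list of `group_comparison` objects, one per metric, with a
#'   `groups` attribute giving the per-subject group labels.
#' @export
module_report <- function(partition, metrics, metric_cols = NULL, sex = NULL,
                          alpha = 0.05) {
  stopifnot(inherits(partition, "module_partition"),
            "subject_id" %in% names(metrics))
  idx <- match(partition$subject_ids, metrics$subject_id)
  if (anyNA(idx))
    stop(sprintf("validation error: metrics missing for subject(s) %s",
                 paste(partition$subject_ids[is.na(idx)], collapse = ", ")))
  metrics <- metrics[idx, , drop = FALSE]
  groups <- if (is.null(sex)) paste0("M", partition$assignment)
            else paste0(substr(sex, 1, 1), partition$assignment)
  if (is.null(metric_cols))
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                                 logical(1))],
                           c("level", "n_unreachable_pairs"))
  out <- lapply(metric_cols, function(col)
    compare_groups(metrics[[col]], groups, alpha = alpha))
  names(out) <- metric_cols
  attr(out, "groups") <- groups
  out
}
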