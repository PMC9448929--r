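#' Construct a structural-connectivity matrix object
#'
#' Validates and wraps one subject's symmetric, nonnegative weighted
#' structural-connectivity (SC) matrix. The diagonal is always stored as 0;
#' small numerical asymmetry (up to `1e-9` relative) is symmetrized away,
#' anything larger is an error.
#'
#' @param W square numeric matrix of nonnegative edge weights.
#' @param parcellation a [parcellation] with `n_nodes == nrow(W)`.
#' @param subject_id subject identifier.
#' @param sex one of `"male"`, `"female"`, `"unspecified"`.
#' @return An object of class `connectome` with fields `subject_id`, `sex`,
#'   `parcellation`, `W`.
#' @export
connectome <- function(W, parcellation, subject_id = "subject",
                       sex = c("unspecified", "male", "female")) {
  sex <- match.arg(sex)
  if (!is.matrix(W) || !is.numeric(W)) stop("W must be a numeric matrix")
  if (nrow(W) != ncol(W)) stop("format error: SC matrix must be square")
  if (nrow(W) != parcellation$n_nodes)
    stop(sprintf("matrix has %d nodes but parcellation '%s' has %d",
                 nrow(W), parcellation$name, parcellation$n_nodes))
  if (anyNA(W) || any(!is.finite(W))) stop("validation error: non-finite entries")
  if (any(W < 0)) stop("validation error: negative edge weights")
  asym <- max(abs(W - t(W)))
  scale <- max(abs(W), 1)
  if (asym > 1e-9 * scale)
    stop(sprintf("validation error: asymmetry %.3g exceeds tolerance", asym))
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- NULL
  structure(list(subject_id = as.character(subject_id)[1L], sex = sex,
                 parcellation = parcellation, W = W),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  ut <- upper_tri_values(x$W)
  cat(sprintf("<connectome> %s (%s): %d nodes [%s], mean edge %.4g, density %.3f\n",
              x$subject_id, x$sex, nrow(x$W), x$parcellation$name,
              mean(ut), mean(ut > 0)))
  invisible(x)
}

# unique off-diagonal entries in fixed row-major upper-triangle order
upper_tri_values <- function(W) {
  idx <- which(upper.tri(W), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  W[idx[ord, , drop = FALSE]]
}

#' Read an SC matrix from a dense text file
#'
#' Accepts whitespace- or tab-delimited square numeric matrices (UTF-8, no
#' header by default). The matrix is validated, symmetrized within the 1e-9
#' tolerance and its diagonal forced to 0.
#'
#' @param path file path.
#' @param parcellation a [parcellation] matching the matrix size.
#' @param subject_id,sex subject metadata.
#' @param header if `TRUE`, skip one header row and one label column.
#' @return A [connectome].
#' @export
read_sc_matrix <- function(path, parcellation, subject_id = basename(path),
                           sex = "unspecified", header = FALSE) {
  tab <- utils::read.table(path, header = header,
                           row.names = if (header) 1L else NULL)
  W <- as.matrix(tab)
  if (!is.numeric(W)) stop("format error: non-numeric entries in SC matrix")
  connectome(W, parcellation, subject_id = subject_id, sex = sex)
}

#' Write an SC matrix as a dense TSV
#' @param cm a [connectome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sc_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectome"))
  utils::write.table(cm$W, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rescale edge weights to a target mean
#'
#' Multiplies all weights by one constant so that the mean of the unique
#' off-diagonal entries (upper triangle) equals `target_mean` exactly. The
#' zero structure is untouched.
#'
#' @param cm a [connectome] with at least one nonzero edge.
#' @param target_mean positive target for the mean unique edge weight.
#' @return A rescaled [connectome].
#' @export
scale_to_target_mean <- function(cm, target_mean = 1e-4) {
  stopifnot(inherits(cm, "connectome"), target_mean > 0)
  m <- mean(upper_tri_values(cm$W))
  if (m == 0) stop("degenerate input: all-zero SC matrix cannot be rescaled")
  cm$W <- cm$W * (target_mean / m)
  cm
}

#' Average fine edges into a coarse system-level matrix
#'
#' Every coarse entry (S, T), S != T, is the mean of all fine edges with one
#' end in S and the other in T; the within-system mean over unique fine pairs
#' inside each system is returned separately as the `within` attribute (the
#' coarse matrix keeps a zero diagonal, matching the convention that only
#' between-system entries enter edge vectors).
#'
#' @param cm a [connectome].
#' @param coarse a [parcellation] whose node labels are the distinct systems
#'   of `cm`'s parcellation (defaults to the induced coarse parcellation).
#' @return A [connectome] on `coarse` with attribute `within`: named vector
#'   of within-system mean weights (0, with a warning, for singleton systems).
#' @export
reparcellate <- function(cm, coarse = induced_coarse_parcellation(cm$parcellation)) {
  stopifnot(inherits(cm, "connectome"), inherits(coarse, "parcellation"))
  fine_sys <- cm$parcellation$systems
  labels <- coarse$systems
  if (!setequal(unique(fine_sys), labels))
    stop("coarse parcellation systems do not match fine parcellation systems")
  k <- length(labels)
  Wc <- matrix(0, k, k)
  within <- stats::setNames(numeric(k), labels)
  for (a in seq_len(k)) {
    ia <- which(fine_sys == labels[a])
    if (length(ia) < 2L) {
      warning(sprintf("system '%s' has < 2 nodes; within-system mean set to 0",
                      labels[a]))
      within[a] <- 0
    } else {
      sub <- cm$W[ia, ia]
      within[a] <- mean(sub[upper.tri(sub)])
    }
    if (a < k) for (b in (a + 1L):k) {
      ib <- which(fine_sys == labels[b])
      Wc[a, b] <- Wc[b, a] <- mean(cm$W[ia, ib])
    }
  }
  out <- connectome(Wc, coarse, subject_id = cm$subject_id, sex = cm$sex)
  attr(out, "within") <- within
  out
}

#' Specify an edge subset
#'
#' @param type `"whole"` (all unique edges), `"within"` (unique fine edges
#'   inside one system) or `"between"` (all fine edges between two distinct
#'   systems).
#' @param system,system2 system labels for `"within"` / `"between"`.
#' @return An `edge_subset` specification.
#' @export
edge_subset <- function(type = c("whole", "within", "between"),
                        system = NULL, system2 = NULL) {
  type <- match.arg(type)
  if (type == "within" && is.null(system))
    stop("within-subset needs a system label")
  if (type == "between") {
    if (is.null(system) || is.null(system2) || system == system2)
      stop("between-subset needs two distinct system labels")
    ss <- sort(c(system, system2))          # canonical: between:S/T == between:T/S
    system <- ss[1L]; system2 <- ss[2L]
  }
  structure(list(type = type, system = system, system2 = system2),
            class = "edge_subset")
}

#' @export
format.edge_subset <- function(x, ...) {
  switch(x$type,
         whole = "whole",
         within = paste0("within:", x$system),
         between = paste0("between:", x$system, "/", x$system2))
}

#' @export
print.edge_subset <- function(x, ...) {
  cat("<edge_subset>", format(x), "\n"); invisible(x)
}

#' Vectorize a connectome's edges
#'
#' Flattens the requested edge subset into a fixed, reproducible order
#' (row-major over the upper triangle, or over the sorted node-index grid
#' for between-subsets), so vectors are comparable across subjects.
#'
#' @param cm a [connectome].
#' @param subset an [edge_subset] (default: whole network).
#' @return An `edge_vector`: list with `subject_id`, `subset` and numeric
#'   `values` (length k(k-1)/2 for the whole upper triangle of a k-node
#'   matrix).
#' @export
vectorize_edges <- function(cm, subset = edge_subset("whole")) {
  stopifnot(inherits(cm, "connectome"), inherits(subset, "edge_subset"))
  p <- cm$parcellation
  values <- switch(
    subset$type,
    whole = upper_tri_values(cm$W),
    within = {
      ia <- system_nodes(p, subset$system)
      if (length(ia) < 2L)
        stop(sprintf("system '%s' has < 2 nodes", subset$system))
      upper_tri_values(cm$W[ia, ia, drop = FALSE])
    },
    between = {
      ia <- system_nodes(p, subset$system)
      ib <- system_nodes(p, subset$system2)
      as.vector(t(cm$W[ia, ib, drop = FALSE]))  # row-major over i in S, j in T
    })
  structure(list(subject_id = cm$subject_id, subset = subset, values = values),
            class = "edge_vector")
}

#' Normalize an SC matrix into a Kuramoto coupling matrix
#'
#' Rescales so that the mean of all n(n-1) off-diagonal elements (structural
#' zeros included) is exactly 1. Idempotent and scale-invariant.
#'
#' @param cm a [connectome] with at least one nonzero edge.
#' @return Numeric coupling matrix (symmetric, nonnegative, zero diagonal).
#' @export
normalize_for_km <- function(cm) {
  stopifnot(inherits(cm, "connectome"))
  W <- cm$W
  n <- nrow(W)
  m <- sum(W) / (n * (n - 1))
  if (m == 0) stop("degenerate input: all-zero SC matrix cannot be normalized")
  W / m
}
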