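#' Create a parcellation
#'
#' A parcellation assigns every node of a connectome to exactly one labelled
#' system. The reference setup nests a 100-node fine scheme inside 7 coarse
#' functional systems (Visual, Somatomotor, DorsalAttention, VentralAttention,
#' Limbic, Control, Default).
#'
#' @param name identifier for the parcellation.
#' @param systems character vector, one system label per node (node i ->
#'   `systems[i]`).
#' @return An object of class `parcellation` with fields `name`, `n_nodes`
#'   and `systems`.
#' @export
parcellation <- function(name, systems) {
  systems <- as.character(systems)
  if (length(systems) < 1L) stop("parcellation needs at least one node")
  if (anyNA(systems) || any(!nzchar(systems)))
    stop("every node must map to exactly one non-empty system label")
  structure(
    list(name = as.character(name)[1L],
         n_nodes = length(systems),
         systems = systems),
    class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s: %d nodes, %d systems\n",
              x$name, x$n_nodes, length(unique(x$systems))))
  print(table(x$systems))
  invisible(x)
}

#' System labels of a parcellation
#' @param p a `parcellation`.
#' @return Character vector of distinct system labels, in order of first
#'   appearance along the node index.
#' @export
system_labels <- function(p) {
  stopifnot(inherits(p, "parcellation"))
  unique(p$systems)
}

#' Node indices belonging to a system
#' @param p a `parcellation`.
#' @param system a system label present in `p`.
#' @return Integer vector of node indices (1-based).
#' @export
system_nodes <- function(p, system) {
  stopifnot(inherits(p, "parcellation"))
  if (!system %in% p$systems)
    stop(sprintf("unknown system label '%s' in parcellation '%s'", system, p$name))
  which(p$systems == system)
}

#' Read a node-to-system parcellation map
#'
#' Expects a two-column TSV `node_index<TAB>system_label` with 0-based node
#' indices and no header. Every node index in `0:(n-1)` must appear exactly
#' once.
#'
#' @param path file path.
#' @param name parcellation name (defaults to the file name).
#' @return A `parcellation`.
#' @export
read_parcellation <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("integer", "character"),
                           col.names = c("node", "system"))
  n <- nrow(tab)
  if (!setequal(tab$node, 0:(n - 1L)))
    stop("node indices must be 0-based and cover 0..(n-1) exactly once")
  systems <- character(n)
  systems[tab$node + 1L] <- tab$system
  parcellation(name, systems)
}

#' Write a parcellation map to TSV
#' @param p a `parcellation`.
#' @param path output path; 0-based node indices, tab-separated.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(p, path) {
  stopifnot(inherits(p, "parcellation"))
  utils::write.table(
    data.frame(node = seq_len(p$n_nodes) - 1L, system = p$systems),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Node counts per system mirroring the Schaefer-100 / Yeo-7 nesting.
.default_system_sizes <- c(
  Visual = 14L, Somatomotor = 16L, DorsalAttention = 13L,
  VentralAttention = 12L, Limbic = 10L, Control = 15L, Default = 20L)

#' Reference fine parcellation (100 nodes, 7 systems)
#'
#' A 100-node parcellation whose nodes are grouped into the 7 canonical
#' functional systems with realistic per-system node counts.
#'
#' @return A `parcellation` with 100 nodes.
#' @export
default_fine_parcellation <- function() {
  parcellation("fine100",
               rep(names(.default_system_sizes), .default_system_sizes))
}

#' Reference coarse parcellation (7 systems, one node each)
#' @return A `parcellation` with 7 nodes, each its own system.
#' @export
default_coarse_parcellation <- function() {
  parcellation("coarse7", names(.default_system_sizes))
}

#' Reduced fine parcellation (7 systems, few nodes each)
#'
#' A desk-scale parcellation with the same 7 systems but
#' `nodes_per_system` nodes in each, for fast dynamics experiments.
#'
#' @param nodes_per_system nodes per system (>= 2).
#' @return A `parcellation` with `7 * nodes_per_system` nodes.
#' @export
small_fine_parcellation <- function(nodes_per_system = 3L) {
  stopifnot(nodes_per_system >= 2L)
  parcellation(sprintf("fine%d", 7L * nodes_per_system),
               rep(names(.default_system_sizes), each = nodes_per_system))
}

#' Coarse parcellation induced by the systems of a fine parcellation
#' @param fine a `parcellation`.
#' @return A `parcellation` with one node per distinct system of `fine`.
#' @export
induced_coarse_parcellation <- function(fine) {
  parcellation(paste0(fine$name, "_systems"), system_labels(fine))
}
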