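# internal helpers shared across modules

# deterministic child seed derived from (master, index); stays below 2^31
derive_seed <- function(master, index, salt = 0L) {
  x <- (as.double(master) %% 2147483647) + 1
  for (v in c(index, salt)) {
    x <- (x * 48271 + as.double(v) + 1) %% 2147483647
    x <- (x * 69621) %% 2147483647
  }
  as.integer(x %% 2147483629) + 1L
}

# evaluate `expr` under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# trapezoidal integral of y over strictly ascending x
trapezoid <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y))
    stop("need at least two (x, y) points of equal length")
  if (any(diff(x) <= 0)) stop("validation error: x must be strictly ascending")
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# relabel a membership vector to 1..k in order of first appearance
canonical_labels <- function(membership) {
  match(membership, unique(membership))
}

# optimal one-to-one mapping of `new` module labels onto `ref` labels by
# maximal total overlap (exhaustive over permutations; module counts here
# are small). Returns the relabelled `new` vector in `ref` label space;
# unmatched new modules keep fresh labels beyond ref's.
map_to_reference <- function(new, ref) {
  nl <- unique(new)
  rl <- unique(ref)
  tab <- matrix(0L, length(nl), length(rl), dimnames = list(nl, rl))
  for (i in seq_along(new))
    tab[match(new[i], nl), match(ref[i], rl)] <-
      tab[match(new[i], nl), match(ref[i], rl)] + 1L
  k <- min(nrow(tab), ncol(tab))
  if (nrow(tab) <= ncol(tab)) {
    perms <- all_injections(nrow(tab), ncol(tab))
    best <- perms[[which.max(vapply(perms, function(p)
      sum(tab[cbind(seq_len(nrow(tab)), p)]), numeric(1)))]]
    mapping <- stats::setNames(rl[best], nl)
  } else {
    perms <- all_injections(ncol(tab), nrow(tab))
    best <- perms[[which.max(vapply(perms, function(p)
      sum(tab[cbind(p, seq_len(ncol(tab)))]), numeric(1)))]]
    mapping <- rep(NA_character_, nrow(tab))
    names(mapping) <- nl
    mapping[best] <- rl
    extra <- which(is.na(mapping))
    if (length(extra))
      mapping[extra] <- paste0("unmatched", seq_along(extra))
  }
  unname(mapping[as.character(new)])
}

# all injective maps 1..k -> 1..n as a list of index vectors
all_injections <- function(k, n) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) { out[[length(out) + 1L]] <<- prefix; return() }
    for (r in remaining) rec(c(prefix, r), setdiff(remaining, r))
  }
  rec(integer(0), seq_len(n))
  out
}
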