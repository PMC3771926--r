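# Statistical grouping: connected components, random splitting of large
# components, maximal clique enumeration, and fractional-Hamming
# redundant-clique elimination.

# Canonical string key of a member set; also the lexicographic tie-break
# order for equal-size cliques.
clique_key <- function(ids) paste(sort(ids), collapse = "\r")

#' Connected components of a connectivity graph
#'
#' @param g An undirected `igraph` graph with named vertices.
#' @return List of character vectors (sorted member ids), ordered by
#'   decreasing size then lexicographically; singletons are the size-1
#'   entries.
#' @export
connected_components <- function(g) {
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  keys <- vapply(comps, `[`, character(1), 1L)
  comps <- comps[order(-lengths(comps), keys)]
  names(comps) <- NULL
  comps
}

#' Randomly split an oversized component into groups
#'
#' Components larger than `max_size` are partitioned uniformly at random
#' into `ceiling(n/max_size)` groups, all of size `max_size` except
#' possibly the last. Deterministic for a fixed seed.
#'
#' @param members Character vector of member ids.
#' @param max_size Maximum group size (default 100).
#' @param seed RNG seed.
#' @return List of character vectors (each sorted).
#' @export
split_large_components <- function(members, max_size = 100, seed = 1) {
  stopifnot(max_size >= 2)
  n <- length(members)
  if (n <= max_size) return(list(sort(members)))
  perm <- with_seed(seed, sample(members))
  idx <- ceiling(seq_len(n) / max_size)
  grps <- split(perm, idx)
  names(grps) <- NULL
  lapply(grps, sort)
}

#' Maximal cliques of a (sub)graph
#'
#' Enumerates all maximal cliques of size at least 2 with the
#' Bron-Kerbosch algorithm (igraph's pivoted implementation), optionally
#' restricted to an induced subgraph.
#'
#' @param g An undirected `igraph` graph with named vertices.
#' @param members Optional character vector restricting `g` to an
#'   induced subgraph.
#' @return List of character vectors (sorted member ids), in canonical
#'   (lexicographic) order.
#' @export
maximal_cliques <- function(g, members = NULL) {
  if (!is.null(members)) {
    g <- igraph::induced_subgraph(g, members)
  }
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) sort(names(v)))
  cl[order(vapply(cl, clique_key, character(1)))]
}

#' Fractional Hamming distance between two cliques
#'
#' The Hamming distance between the two membership vectors (the size of
#' the symmetric difference of the member sets) divided by the total
#' number of sequences in both cliques, removing the effect of clique
#' size on the distance.
#'
#' @param a,b Character vectors of member ids.
#' @return Distance in `[0, 1]`.
#' @export
fractional_hamming <- function(a, b) {
  mismatches <- length(setdiff(a, b)) + length(setdiff(b, a))
  mismatches / (length(a) + length(b))
}

#' Eliminate redundant cliques
#'
#' Clusters cliques by single linkage over pairs with fractional Hamming
#' distance at or below `threshold`, and keeps only the largest clique
#' of each cluster (ties broken by the lexicographically smallest sorted
#' member-id set).
#'
#' @param cliques List of character vectors of member ids.
#' @param threshold Fractional Hamming distance threshold (default 0.3).
#' @return List of surviving cliques, in canonical order.
#' @export
eliminate_redundant <- function(cliques, threshold = 0.3) {
  stopifnot(threshold > 0, threshold < 1)
  k <- length(cliques)
  if (k <= 1) return(cliques)
  sets <- lapply(cliques, unique)
  sizes <- lengths(sets)
  # single-linkage clusters = connected components of the near-duplicate
  # graph
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      h <- (sizes[i] + sizes[j] - 2 * inter) / (sizes[i] + sizes[j])
      if (h <= threshold) {
        edges_from <- c(edges_from, i)
        edges_to <- c(edges_to, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  memb <- igraph::components(g)$membership
  keys <- vapply(sets, clique_key, character(1))
  reps <- vapply(split(seq_len(k), memb), function(ix) {
    ix[order(-sizes[ix], keys[ix])][1]
  }, integer(1))
  out <- cliques[reps]
  out[order(vapply(out, clique_key, character(1)))]
}
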