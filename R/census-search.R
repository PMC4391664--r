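#' Find a matching realizing a prescribed component census
#'
#' Searches, in deterministic lexicographic order, over all injective
#' assignments of the genes of A to genes of B of a given size for a
#' matching whose weighted adjacency graph of reduced genomes has the
#' prescribed numbers of cycles and odd paths. Used to reconstruct
#' worked-example matchings when only the component census, not the edge
#' set, is pinned down.
#'
#' @param A,B [genome()] objects with disjoint gene sets.
#' @param size matching size (must not exceed either gene count).
#' @param cycles,odd_paths the target census.
#' @param weights numeric vector of length `size`: edge weights assigned,
#'   in label order, to the matching found.
#' @return The matching data.frame, or `NULL` when no assignment realizes
#'   the census.
#' @export
search_matching_by_census <- function(A, B, size, cycles, odd_paths,
                                      weights = rep(1, size)) {
  stopifnot(length(weights) == size)
  ga <- gene_set(A)
  gb <- gene_set(B)
  stopifnot(size <= length(ga), size <= length(gb))
  a_sel <- utils::combn(ga, size, simplify = FALSE)
  for (aa in a_sel) {
    for (bb in permutations_of(gb, size)) {
      M <- data.frame(gene_a = aa, gene_b = bb, sigma = weights)
      R <- reduce_genomes(A, B, M)
      comps <- decompose_components(build_weighted_adjacency_graph(R))
      k <- census_counts(comps)
      if (k$c == cycles && k$i == odd_paths) return(as_matching(M))
    }
  }
  NULL
}

# all ordered size-m selections from v, lexicographic, as a list
permutations_of <- function(v, m) {
  if (m == 0L) return(list(character()))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(prefix) == m) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (i in seq_along(rest)) {
      rec(c(prefix, rest[i]), rest[-i])
    }
    invisible(NULL)
  }
  rec(character(), v)
  out
}
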