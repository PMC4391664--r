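#' Build the adjacency graph of two genomes
#'
#' The adjacency graph AG(A, B) is a bipartite multigraph whose two vertex
#' classes are the adjacencies of A and of B, with one edge per gene
#' extremity connecting the two adjacencies that contain it. Both genomes
#' must be duplication-free and have identical gene sets. Every vertex has
#' degree one (telomeric adjacency) or two, so the graph decomposes into
#' paths and cycles.
#'
#' @param A,B duplication-free [genome()] objects with equal gene sets.
#' @param weights optional named numeric vector giving, per gene name, the
#'   weight carried by both of that gene's extremity edges (used for the
#'   weighted adjacency graph of reduced genomes). Unweighted edges carry
#'   `NA`.
#' @return An object of class `"adjacency_graph"`: list with `adj_A`,
#'   `adj_B` (adjacency lists as in [genome_adjacencies()]), `edges`
#'   (data.frame `a`, `b`, `extremity`, `weight`) and `n` (gene count).
#' @export
build_adjacency_graph <- function(A, B, weights = NULL) {
  validate_genome(A)
  validate_genome(B)
  ga <- sort(gene_set(A))
  gb <- sort(gene_set(B))
  if (!identical(ga, gb)) {
    stop("genomes must have identical gene sets", call. = FALSE)
  }
  adj_A <- genome_adjacencies(A)
  adj_B <- genome_adjacencies(B)
  locate <- function(adjs) {
    ext <- unlist(adjs, use.names = FALSE)
    idx <- rep(seq_along(adjs), lengths(adjs))
    stats::setNames(idx, ext)
  }
  locA <- locate(adj_A)
  locB <- locate(adj_B)
  exts <- as.character(outer(ga, c("t", "h"), extremity))
  w <- if (is.null(weights)) rep(NA_real_, length(exts)) else {
    unname(weights[sub(":(t|h)$", "", exts)])
  }
  edges <- data.frame(a = unname(locA[exts]), b = unname(locB[exts]),
                      extremity = exts, weight = w,
                      stringsAsFactors = FALSE)
  structure(list(adj_A = adj_A, adj_B = adj_B, edges = edges,
                 n = length(ga)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cc <- decompose_components(x)
  cat("Adjacency graph:", x$n, "genes,",
      length(x$adj_A), "+", length(x$adj_B), "adjacencies,",
      nrow(x$edges), "edges;",
      sum(cc$kind == "cycle"), "cycle(s),",
      sum(cc$kind == "odd_path"), "odd path(s),",
      sum(cc$kind == "even_path"), "even path(s)\n")
  invisible(x)
}

#' Decompose an adjacency graph into components
#'
#' Components are classified as cycles, odd paths or even paths; the
#' length |C| of a component is its number of edges and the lengths sum to
#' 2n over the whole graph. For weighted graphs, `weight` is the sum of
#' the edge weights w(C).
#'
#' @param g an `"adjacency_graph"` from [build_adjacency_graph()].
#' @return data.frame with one row per component, columns `kind`
#'   (`"cycle"`, `"odd_path"`, `"even_path"`), `length` and `weight`
#'   (`NA` for unweighted graphs), ordered by smallest incident edge
#'   label for reproducibility.
#' @export
decompose_components <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"))
  e <- g$edges
  if (nrow(e) == 0L) {
    return(data.frame(kind = character(), length = integer(),
                      weight = numeric()))
  }
  va <- paste0("A", e$a)
  vb <- paste0("B", e$b)
  verts <- unique(c(paste0("A", seq_along(g$adj_A)),
                    paste0("B", seq_along(g$adj_B))))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = va, to = vb, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  memb <- igraph::components(ig)$membership
  comp_of_edge <- unname(memb[va])
  nv <- table(memb)
  ne <- table(comp_of_edge)
  ids <- sort(unique(comp_of_edge))
  len <- as.integer(ne[as.character(ids)])
  nvert <- as.integer(nv[as.character(ids)])
  kind <- ifelse(len == nvert, "cycle",
                 ifelse(len %% 2L == 1L, "odd_path", "even_path"))
  w <- if (all(is.na(e$weight))) rep(NA_real_, length(ids)) else {
    vapply(ids, function(id) sum(e$weight[comp_of_edge == id]), numeric(1))
  }
  first_ext <- vapply(ids, function(id) min(e$extremity[comp_of_edge == id]),
                      character(1))
  ord <- order(first_ext, method = "radix")
  data.frame(kind = kind[ord], length = len[ord], weight = w[ord])
}

#' Per-component contribution to the DCJ distance
#'
#' A cycle contributes |C|/2 - 1, an odd path (|C| - 1)/2 and an even
#' path |C|/2 to the family-based DCJ distance.
#'
#' @param kind character vector of component kinds (`"cycle"`,
#'   `"odd_path"`, `"even_path"`), or the data.frame returned by
#'   [decompose_components()].
#' @param length integer vector of component lengths (ignored when `kind`
#'   is a data.frame).
#' @return numeric vector of contributions d(C).
#' @export
component_contribution <- function(kind, length = NULL) {
  if (is.data.frame(kind)) {
    length <- kind$length
    kind <- kind$kind
  }
  stopifnot(base::length(kind) == base::length(length))
  ifelse(kind == "cycle", length / 2 - 1,
         ifelse(kind == "odd_path", (length - 1) / 2, length / 2))
}

census_counts <- function(comps) {
  list(c = sum(comps$kind == "cycle"),
       i = sum(comps$kind == "odd_path"),
       even = sum(comps$kind == "even_path"))
}

#' Family-based DCJ distance of duplication-free genomes
#'
#' Computes d_DCJ(A, B) = n - c - i/2, where n is the number of genes, c
#' the number of cycles and i the number of odd paths of the adjacency
#' graph. The same value is recomputed as the sum of per-component
#' contributions and both routes are asserted to agree; the result is
#' asserted to be a non-negative integer.
#'
#' @param A,B duplication-free [genome()] objects with equal gene sets.
#' @return The distance as a single number. With `census = TRUE`, a list
#'   `list(distance, n, c, i, even)`.
#' @param census logical; return the component census alongside.
#' @examples
#' A <- genome("A", chromosome(c("-1", "3", "4", "2")))
#' B <- genome("B", chromosome(c("-2", "1", "4", "3")))
#' dcj_distance(A, B)  # 2
#' @export
dcj_distance <- function(A, B, census = FALSE) {
  n <- n_genes(A)
  if (n == 0L && n_genes(B) == 0L) {
    out <- list(distance = 0, n = 0L, c = 0L, i = 0L, even = 0L)
    return(if (census) out else out$distance)
  }
  comps <- decompose_components(build_adjacency_graph(A, B))
  k <- census_counts(comps)
  d <- n - k$c - k$i / 2
  d_sum <- sum(component_contribution(comps))
  if (abs(d - d_sum) > 1e-9) {
    stop("internal error: component-sum route disagrees with n - c - i/2",
         call. = FALSE)
  }
  if (abs(d - round(d)) > 1e-9 || d < -1e-9) {
    stop("internal error: DCJ distance must be a non-negative integer",
         call. = FALSE)
  }
  d <- round(d)
  if (census) list(distance = d, n = n, c = k$c, i = k$i, even = k$even)
  else d
}
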