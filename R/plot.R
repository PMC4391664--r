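#' Plot a gene similarity graph
#'
#' Draws the weighted bipartite gene similarity graph with the genes of A
#' on top and the genes of B below, edge labels showing sigma.
#'
#' @param x a `"gs_graph"`.
#' @param ... passed on to [igraph::plot.igraph()].
#' @export
plot.gs_graph <- function(x, ...) {
  verts <- data.frame(name = c(paste0("A.", x$genes_a),
                               paste0("B.", x$genes_b)),
                      label = c(x$genes_a, x$genes_b),
                      type = rep(c(FALSE, TRUE),
                                 c(length(x$genes_a), length(x$genes_b))))
  ed <- data.frame(from = paste0("A.", x$edges$gene_a),
                   to = paste0("B.", x$edges$gene_b))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
  igraph::plot.igraph(
    g, layout = igraph::layout_as_bipartite(g),
    vertex.label = igraph::V(g)$label, vertex.size = 18,
    edge.label = signif(x$edges$sigma, 3), ...)
  invisible(x)
}

#' Plot an adjacency graph
#'
#' Draws the bipartite adjacency graph with A-adjacencies on top and
#' B-adjacencies below; one edge per gene extremity.
#'
#' @param x an `"adjacency_graph"`.
#' @param ... passed on to [igraph::plot.igraph()].
#' @export
plot.adjacency_graph <- function(x, ...) {
  lab <- function(adjs) vapply(adjs, paste, character(1), collapse = " ")
  verts <- data.frame(name = c(paste0("A", seq_along(x$adj_A)),
                               paste0("B", seq_along(x$adj_B))),
                      label = c(lab(x$adj_A), lab(x$adj_B)),
                      type = rep(c(FALSE, TRUE),
                                 c(length(x$adj_A), length(x$adj_B))))
  ed <- data.frame(from = paste0("A", x$edges$a),
                   to = paste0("B", x$edges$b))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
  igraph::plot.igraph(
    g, layout = igraph::layout_as_bipartite(g),
    vertex.label = igraph::V(g)$label, vertex.size = 22,
    vertex.shape = "rectangle", ...)
  invisible(x)
}
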