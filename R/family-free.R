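#' Parse or validate a gene similarity table
#'
#' The similarity table holds the normalized gene similarity sigma(a, b)
#' in (0, 1] for pairs of genes across the two genomes; absent pairs mean
#' sigma = 0 (no edge). In the family-free setting the gene sets of the
#' two genomes must be disjoint.
#'
#' `parse_similarities()` reads a three-column TSV (`gene_a`, `gene_b`,
#' `sigma`, no header); `similarity_table()` validates an existing
#' data.frame. Rows with sigma exactly 0 are dropped (they carry no
#' edge); sigma outside \[0, 1\] is an error, as are duplicate pairs,
#' gene names unknown to either genome, and gene names present in both
#' genomes.
#'
#' @param text TSV text, file path or `"-"` (stdin), as in
#'   [parse_genomes()].
#' @param df data.frame with columns `gene_a`, `gene_b`, `sigma`.
#' @param A,B [genome()] objects with disjoint gene sets.
#' @return data.frame of class `"similarity_table"` with columns
#'   `gene_a`, `gene_b`, `sigma`.
#' @export
parse_similarities <- function(text, A, B) {
  lines <- read_input_lines(text)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(similarity_table(data.frame(gene_a = character(),
                                       gene_b = character(),
                                       sigma = numeric()), A, B))
  }
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          colClasses = c("character", "character", "numeric"),
                          col.names = c("gene_a", "gene_b", "sigma"),
                          quote = "", comment.char = "")
  similarity_table(df, A, B)
}

#' @rdname parse_similarities
#' @export
similarity_table <- function(df, A, B) {
  stopifnot(is.data.frame(df),
            all(c("gene_a", "gene_b", "sigma") %in% names(df)))
  df <- df[, c("gene_a", "gene_b", "sigma")]
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$sigma <- as.numeric(df$sigma)
  ga <- gene_set(A)
  gb <- gene_set(B)
  both <- intersect(ga, gb)
  if (length(both) > 0L) {
    stop("family-free input requires disjoint gene sets; shared name(s): ",
         paste(utils::head(both, 3L), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$sigma) | df$sigma < 0 | df$sigma > 1)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  bad_a <- setdiff(df$gene_a, ga)
  bad_b <- setdiff(df$gene_b, gb)
  if (length(bad_a) || length(bad_b)) {
    stop("similarity table references unknown gene(s): ",
         paste(utils::head(c(bad_a, bad_b), 3L), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate gene pair in similarity table", call. = FALSE)
  }
  df <- df[df$sigma > 0, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("similarity_table", "data.frame")
  df
}

#' Build the gene similarity graph
#'
#' The gene similarity graph GS_sigma(A, B) is the weighted bipartite
#' graph whose parts are the gene sets of A and B, with an edge of weight
#' sigma(a, b) for every positive similarity entry.
#'
#' @param A,B [genome()] objects with disjoint gene sets.
#' @param S a `"similarity_table"` (see [similarity_table()]), or a
#'   data.frame coercible to one.
#' @return An object of class `"gs_graph"`: list with `genes_a`,
#'   `genes_b` and `edges` (data.frame `gene_a`, `gene_b`, `sigma`).
#' @export
build_gs_graph <- function(A, B, S) {
  validate_genome(A)
  validate_genome(B)
  if (!inherits(S, "similarity_table")) S <- similarity_table(S, A, B)
  structure(list(genes_a = gene_set(A), genes_b = gene_set(B),
                 edges = as.data.frame(S)),
            class = "gs_graph")
}

#' @export
print.gs_graph <- function(x, ...) {
  cat("Gene similarity graph:", length(x$genes_a), "+", length(x$genes_b),
      "genes,", nrow(x$edges), "edge(s)\n")
  invisible(x)
}

#' Matchings of the gene similarity graph
#'
#' A matching is a set of pairwise non-adjacent edges of the gene
#' similarity graph, represented as a data.frame with columns `gene_a`,
#' `gene_b`, `sigma`. `as_matching()` validates the representation,
#' `matching_weight()` returns w(M) (the sum of its edge weights), and
#' `is_maximal_matching()` tests whether no further graph edge could be
#' added, i.e. every edge of the graph has at least one endpoint
#' saturated by M.
#'
#' @param M a data.frame with columns `gene_a`, `gene_b` and optionally
#'   `sigma`.
#' @param G a `"gs_graph"`; when given to `as_matching()`, edges are
#'   checked for membership and missing sigmas filled in.
#' @return `as_matching()`: the validated matching data.frame;
#'   `matching_weight()`: a number; `is_maximal_matching()`: logical.
#' @export
as_matching <- function(M, G = NULL) {
  stopifnot(is.data.frame(M), all(c("gene_a", "gene_b") %in% names(M)))
  M <- as.data.frame(M)
  M$gene_a <- as.character(M$gene_a)
  M$gene_b <- as.character(M$gene_b)
  if (anyDuplicated(M$gene_a) || anyDuplicated(M$gene_b)) {
    stop("not a matching: repeated endpoint", call. = FALSE)
  }
  if (!is.null(G)) {
    stopifnot(inherits(G, "gs_graph"))
    gk <- paste(G$edges$gene_a, G$edges$gene_b, sep = "\r")
    mk <- paste(M$gene_a, M$gene_b, sep = "\r")
    pos <- match(mk, gk)
    if (anyNA(pos)) {
      stop("matching contains edge(s) absent from the gene similarity graph",
           call. = FALSE)
    }
    M$sigma <- G$edges$sigma[pos]
  }
  if (is.null(M$sigma)) {
    stop("matching needs a sigma column (or pass the graph G)", call. = FALSE)
  }
  M <- M[, c("gene_a", "gene_b", "sigma")]
  rownames(M) <- NULL
  M
}

#' @rdname as_matching
#' @export
matching_weight <- function(M) sum(as.numeric(M$sigma))

#' @rdname as_matching
#' @export
is_maximal_matching <- function(G, M) {
  stopifnot(inherits(G, "gs_graph"))
  M <- as_matching(M, G)
  if (nrow(G$edges) == 0L) return(TRUE)
  all(G$edges$gene_a %in% M$gene_a | G$edges$gene_b %in% M$gene_b)
}

#' Reduce two genomes under a matching
#'
#' Given a matching M of the gene similarity graph, the reduced genomes
#' A^M and B^M are obtained by deleting all unsaturated genes and
#' renaming each matched pair to a shared label in 1..|M|, preserving
#' orientations. Chromosomes left empty are dropped. Labels are assigned
#' in order of the matched gene's first occurrence along A (chromosome
#' order, then position), a fixed rule that makes output reproducible;
#' the label bijection is otherwise arbitrary and does not affect any
#' distance or similarity value.
#'
#' @param A,B [genome()] objects with disjoint gene sets.
#' @param M a matching (see [as_matching()]); every `gene_a` must occur in
#'   A and every `gene_b` in B.
#' @return An object of class `"reduced_genomes"`: list with genomes `A`
#'   and `B` over the gene set 1..|M|, the labeled `matching` (extra
#'   column `label`), and `sigma`, the per-label weight vector.
#' @export
reduce_genomes <- function(A, B, M) {
  validate_genome(A)
  validate_genome(B)
  M <- as_matching(M)
  if (!all(M$gene_a %in% gene_set(A)) || !all(M$gene_b %in% gene_set(B))) {
    stop("matching references genes absent from the genomes", call. = FALSE)
  }
  a_order <- unlist(lapply(A$chromosomes, `[[`, "genes"), use.names = FALSE)
  M <- M[order(match(M$gene_a, a_order)), , drop = FALSE]
  M$label <- seq_len(nrow(M))
  rownames(M) <- NULL
  lab_a <- stats::setNames(M$label, M$gene_a)
  lab_b <- stats::setNames(M$label, M$gene_b)

  relabel <- function(G, lab) {
    chroms <- list()
    for (ch in G$chromosomes) {
      keep <- ch$genes %in% names(lab)
      if (!any(keep)) next
      chroms[[length(chroms) + 1L]] <- structure(
        list(genes = as.character(lab[ch$genes[keep]]),
             signs = ch$signs[keep], circular = ch$circular),
        class = "chromosome")
    }
    genome(G$name, chroms)
  }

  structure(list(A = relabel(A, lab_a), B = relabel(B, lab_b),
                 matching = M,
                 sigma = stats::setNames(M$sigma, as.character(M$label))),
            class = "reduced_genomes")
}

#' @export
print.reduced_genomes <- function(x, ...) {
  cat("Reduced genome pair: |M| =", nrow(x$matching),
      " w(M) =", format(matching_weight(x$matching)), "\n")
  invisible(x)
}

#' Weighted adjacency graph of reduced genomes
#'
#' The adjacency graph of A^M and B^M in which both extremity edges of
#' gene i carry the weight sigma(e_i) of the matching edge that created
#' label i. Its total edge weight is exactly twice the matching weight,
#' which is asserted.
#'
#' @param R a `"reduced_genomes"` object from [reduce_genomes()].
#' @return An `"adjacency_graph"` with per-edge weights.
#' @export
build_weighted_adjacency_graph <- function(R) {
  stopifnot(inherits(R, "reduced_genomes"))
  if (nrow(R$matching) == 0L) {
    return(structure(list(adj_A = list(), adj_B = list(),
                          edges = data.frame(a = integer(), b = integer(),
                                             extremity = character(),
                                             weight = numeric()),
                          n = 0L),
                     class = "adjacency_graph"))
  }
  g <- build_adjacency_graph(R$A, R$B, weights = R$sigma)
  total <- sum(g$edges$weight)
  if (abs(total - 2 * matching_weight(R$matching)) > 1e-9) {
    stop("internal error: weighted adjacency graph weight != 2 w(M)",
         call. = FALSE)
  }
  g
}

#' Per-component contribution to the family-free DCJ distance
#'
#' Components of the weighted adjacency graph contribute through
#' f(C) = 2|C| - w(C), the simplest linear function that equals |C| when
#' all weights are 1 and grows as weights shrink: a cycle contributes
#' (2|C| - w(C))/2 - 1, an odd path (2|C| - w(C) - 1)/2 and an even path
#' (2|C| - w(C))/2. With all weights 1 this reduces to
#' [component_contribution()].
#'
#' @param kind component kinds, or the data.frame from
#'   [decompose_components()].
#' @param length,weight integer / numeric vectors (ignored when `kind` is
#'   a data.frame).
#' @return numeric vector of contributions d_sigma(C).
#' @export
weighted_component_contribution <- function(kind, length = NULL,
                                            weight = NULL) {
  if (is.data.frame(kind)) {
    length <- kind$length
    weight <- kind$weight
    kind <- kind$kind
  }
  f <- 2 * length - weight
  ifelse(kind == "cycle", f / 2 - 1,
         ifelse(kind == "odd_path", (f - 1) / 2, f / 2))
}

#' Family-free DCJ distance of reduced genomes
#'
#' Evaluates d_sigma(A^M, B^M) for a fixed matching M: the sum of the
#' weighted component contributions of the weighted adjacency graph,
#' which equals d_DCJ(A^M, B^M) + |M| - w(M). Both routes are computed
#' and an internal-consistency error is raised if they differ beyond
#' 1e-9, guarding against component-classification bugs.
#'
#' @param R a `"reduced_genomes"` object.
#' @return The distance d_sigma as a single non-negative number.
#' @export
dsigma <- function(R) {
  stopifnot(inherits(R, "reduced_genomes"))
  m <- nrow(R$matching)
  if (m == 0L) return(0)
  comps <- decompose_components(build_weighted_adjacency_graph(R))
  route1 <- sum(weighted_component_contribution(comps))
  k <- census_counts(comps)
  d_dcj <- m - k$c - k$i / 2
  route2 <- d_dcj + m - matching_weight(R$matching)
  if (abs(route1 - route2) > 1e-9) {
    stop("internal error: d_sigma component sum != d_DCJ + |M| - w(M)",
         call. = FALSE)
  }
  route1
}

#' Family-free DCJ similarity of reduced genomes
#'
#' The normalized total weight of all components of the weighted
#' adjacency graph: cycles contribute w(C)/|C|, odd paths w(C)/(|C| + 1)
#' and even paths w(C)/(|C| + 2).
#'
#' @param R a `"reduced_genomes"` object.
#' @return The similarity s_sigma as a single non-negative number.
#' @export
ssigma <- function(R) {
  stopifnot(inherits(R, "reduced_genomes"))
  if (nrow(R$matching) == 0L) return(0)
  comps <- decompose_components(build_weighted_adjacency_graph(R))
  denom <- comps$length + ifelse(comps$kind == "cycle", 0L,
                                 ifelse(comps$kind == "odd_path", 1L, 2L))
  sum(comps$weight / denom)
}

#' Parameterized similarity F_alpha
#'
#' The convex combination F_alpha = alpha * s_sigma + (1 - alpha) * w(M):
#' alpha near 0 favors raw gene similarity (maximum-weight matching),
#' alpha near 1 favors genome-organization similarity.
#'
#' @param R a `"reduced_genomes"` object.
#' @param alpha a number in \[0, 1\].
#' @return The value of F_alpha.
#' @export
f_alpha <- function(R, alpha) {
  stopifnot(inherits(R, "reduced_genomes"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a number in [0, 1]", call. = FALSE)
  }
  alpha * ssigma(R) + (1 - alpha) * matching_weight(R$matching)
}
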