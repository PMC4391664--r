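#' Enumerate all maximal matchings of a gene similarity graph
#'
#' Depth-first enumeration over the edge list: each edge is either
#' excluded or, if both endpoints are free, included; at the leaves,
#' matchings in which some graph edge still has two unsaturated endpoints
#' are discarded. Every maximal matching is produced exactly once. The
#' edgeless graph has exactly one maximal matching, the empty one.
#'
#' @param G a `"gs_graph"` from [build_gs_graph()].
#' @param cap maximum number of search states before giving up with an
#'   error (signalling that the ILP solver should be used instead).
#' @return A list of matchings (data.frames `gene_a`, `gene_b`, `sigma`).
#' @export
enumerate_maximal_matchings <- function(G, cap = 2^20) {
  stopifnot(inherits(G, "gs_graph"))
  e <- G$edges
  m <- nrow(e)
  empty <- e[0, , drop = FALSE]
  if (m == 0L) return(list(empty))
  res <- list()
  states <- 0L
  rec <- function(i, used_a, used_b, chosen) {
    states <<- states + 1L
    if (states > cap) {
      stop("enumeration cap exceeded (", cap, " states); use the ILP solver",
           call. = FALSE)
    }
    if (i > m) {
      maximal <- all(e$gene_a %in% used_a | e$gene_b %in% used_b)
      if (maximal) {
        M <- e[chosen, , drop = FALSE]
        rownames(M) <- NULL
        res[[length(res) + 1L]] <<- M
      }
      return(invisible(NULL))
    }
    free <- !(e$gene_a[i] %in% used_a) && !(e$gene_b[i] %in% used_b)
    if (free) {
      rec(i + 1L, c(used_a, e$gene_a[i]), c(used_b, e$gene_b[i]),
          c(chosen, i))
    }
    rec(i + 1L, used_a, used_b, chosen)
    invisible(NULL)
  }
  rec(1L, character(), character(), integer())
  res
}

#' Family-free DCJ distance by brute force
#'
#' Reference solver: enumerates every maximal matching of the gene
#' similarity graph and minimizes d_sigma of the reduced genomes. With no
#' edges, the empty matching is the unique maximal matching and the
#' distance is 0.
#'
#' @param A,B [genome()] objects with disjoint gene sets.
#' @param S a similarity table (see [similarity_table()]).
#' @param cap search-state cap passed to [enumerate_maximal_matchings()].
#' @return list with `distance`, the optimal `matching`, and
#'   `n_maximal`, the number of maximal matchings examined.
#' @export
ffdcj_distance_bruteforce <- function(A, B, S, cap = 2^20) {
  G <- build_gs_graph(A, B, S)
  Ms <- enumerate_maximal_matchings(G, cap = cap)
  best <- NULL
  best_d <- Inf
  for (M in Ms) {
    d <- dsigma(reduce_genomes(A, B, M))
    if (d < best_d - 1e-12) {
      best_d <- d
      best <- M
    }
  }
  list(distance = best_d, matching = best, n_maximal = length(Ms))
}

#' Family-free DCJ similarity by brute force
#'
#' Enumerates every maximal matching and maximizes s_sigma of the reduced
#' genomes.
#'
#' @inheritParams ffdcj_distance_bruteforce
#' @return list with `similarity`, the optimal `matching`, and
#'   `n_maximal`.
#' @export
ffdcj_similarity_bruteforce <- function(A, B, S, cap = 2^20) {
  G <- build_gs_graph(A, B, S)
  Ms <- enumerate_maximal_matchings(G, cap = cap)
  best <- NULL
  best_s <- -Inf
  for (M in Ms) {
    s <- ssigma(reduce_genomes(A, B, M))
    if (s > best_s + 1e-12) {
      best_s <- s
      best <- M
    }
  }
  if (!is.finite(best_s)) best_s <- 0
  list(similarity = best_s, matching = best, n_maximal = length(Ms))
}

#' Exemplar DCJ distance by brute force
#'
#' For genomes with duplicated genes (families occurring more than once),
#' enumerates every way of keeping exactly one occurrence per family in
#' each genome and minimizes the family-based DCJ distance over the
#' resulting exemplar pairs. Every family must occur in both genomes.
#'
#' @param A,B [genome()] objects over a common family alphabet, possibly
#'   with duplicates.
#' @param cap maximum number of exemplar pairs to enumerate.
#' @return list with `distance`, exemplar genomes `A_x` and `B_x`, and
#'   `n_pairs`, the number of exemplar pairs examined.
#' @export
exemplar_dcj_bruteforce <- function(A, B, cap = 2^16) {
  validate_genome(A, allow_duplicates = TRUE)
  validate_genome(B, allow_duplicates = TRUE)
  fams <- sort(unique(c(gene_set(A), gene_set(B))))
  occA <- gene_occurrences(A)
  occB <- gene_occurrences(B)
  missing_a <- setdiff(fams, occA$gene)
  missing_b <- setdiff(fams, occB$gene)
  if (length(missing_a) || length(missing_b)) {
    stop("family absent from one genome: ",
         paste(utils::head(c(missing_a, missing_b), 3L), collapse = ", "),
         call. = FALSE)
  }
  slots <- function(occ) lapply(fams, function(f) which(occ$gene == f))
  sA <- slots(occA)
  sB <- slots(occB)
  n_pairs <- prod(lengths(sA)) * prod(lengths(sB))
  if (n_pairs > cap) {
    stop("exemplar enumeration cap exceeded (", n_pairs, " > ", cap, ")",
         call. = FALSE)
  }
  pick <- function(G, occ, keep_rows) {
    keep <- logical(nrow(occ))
    keep[keep_rows] <- TRUE
    chroms <- list()
    for (ci in seq_along(G$chromosomes)) {
      ch <- G$chromosomes[[ci]]
      sel <- keep[occ$chromosome == ci]
      if (!any(sel)) next
      chroms[[length(chroms) + 1L]] <- structure(
        list(genes = ch$genes[sel], signs = ch$signs[sel],
             circular = ch$circular),
        class = "chromosome")
    }
    genome(G$name, chroms)
  }
  combos <- function(s) {
    grid <- do.call(expand.grid, c(s, list(KEEP.OUT.ATTRS = FALSE)))
    lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
  }
  best <- NULL
  best_d <- Inf
  for (ka in combos(sA)) {
    A_x <- pick(A, occA, ka)
    for (kb in combos(sB)) {
      B_x <- pick(B, occB, kb)
      d <- dcj_distance(A_x, B_x)
      if (d < best_d) {
        best_d <- d
        best <- list(A_x = A_x, B_x = B_x)
      }
    }
  }
  list(distance = best_d, A_x = best$A_x, B_x = best$B_x, n_pairs = n_pairs)
}
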