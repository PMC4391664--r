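#' Build the ILP model for the family-free DCJ distance
#'
#' Constructs the graph H on the extremity sets X_A and X_B of the two
#' genomes, with three edge classes: matching edges E_m (two per gene
#' similarity edge, one head-head and one tail-tail, weight sigma),
#' adjacency edges E_a (weight 1, one per non-telomeric adjacency, forced
#' into every solution) and self edges E_s (weight 0, connecting the two
#' extremities of one gene; choosing both of a gene's extremity-
#' incidences of its self edge excises the gene). On top of H sit the
#' binary edge variables x_e and the constraint families: forced
#' adjacency edges; exactly one chosen E_m/E_s edge per vertex;
#' head/tail consistency per similarity edge; maximality (the two self
#' edges of a similarity edge's endpoints cannot both be chosen); and the
#' label/counter variables y_i, z_i that count cycles. Vertices are
#' indexed with all of X_A before X_B so that counter variables are only
#' needed on X_A.
#'
#' Genes with no similarity edge are removed before building H: they can
#' only be excised, and their extremities would otherwise form
#' matching-free components that the cycle counter must not credit.
#'
#' @param A,B [genome()] objects with disjoint gene sets.
#' @param S a similarity table (see [similarity_table()]).
#' @return An object of class `"ilp_model"`; see Details. Use
#'   [solve_distance()] to solve it and [ilp_write_lp()] to export it in
#'   LP format for an external solver.
#' @export
build_distance_ilp <- function(A, B, S) {
  G <- build_gs_graph(A, B, S)
  gs <- G$edges
  keepA <- intersect(gene_set(A), gs$gene_a)
  keepB <- intersect(gene_set(B), gs$gene_b)
  strip <- function(Gnm, keep) {
    chroms <- list()
    for (ch in Gnm$chromosomes) {
      sel <- ch$genes %in% keep
      if (!any(sel)) next
      chroms[[length(chroms) + 1L]] <- structure(
        list(genes = ch$genes[sel], signs = ch$signs[sel],
             circular = ch$circular), class = "chromosome")
    }
    genome(Gnm$name, chroms)
  }
  A_w <- strip(A, keepA)
  B_w <- strip(B, keepB)

  vert <- function(Gnm, side_tag) {
    occ <- gene_occurrences(Gnm)
    if (nrow(occ) == 0L) {
      return(data.frame(genome = character(), gene = character(),
                        side = character(), label = character()))
    }
    data.frame(genome = side_tag,
               gene = rep(occ$gene, each = 2L),
               side = rep(c("t", "h"), times = nrow(occ)),
               label = as.vector(rbind(extremity(occ$gene, "t"),
                                       extremity(occ$gene, "h"))),
               stringsAsFactors = FALSE)
  }
  va <- vert(A_w, "A")
  vb <- vert(B_w, "B")
  vertices <- rbind(va, vb)
  k <- nrow(vertices)
  vid <- function(side_tag, label) {
    which(vertices$genome == side_tag & vertices$label == label)
  }
  idxA <- stats::setNames(seq_len(nrow(va)), va$label)
  idxB <- stats::setNames(nrow(va) + seq_len(nrow(vb)), vb$label)

  # forced adjacency edges: non-telomeric adjacencies within each genome
  adjp <- integer(k)
  e_a <- list()
  add_adj <- function(Gnm, idx) {
    for (ad in genome_adjacencies(Gnm)) {
      if (length(ad) == 2L) {
        i <- idx[[ad[1L]]]
        j <- idx[[ad[2L]]]
        adjp[i] <<- j
        adjp[j] <<- i
        e_a[[length(e_a) + 1L]] <<- c(i, j)
      }
    }
  }
  if (nrow(va) > 0L) add_adj(A_w, idxA)
  if (nrow(vb) > 0L) add_adj(B_w, idxB)

  # self edges, one per gene
  self_of <- function(idx, genes) {
    cbind(unname(idx[extremity(genes, "t")]), unname(idx[extremity(genes, "h")]))
  }
  e_s <- rbind(if (length(keepA)) self_of(idxA, keepA),
               if (length(keepB)) self_of(idxB, keepB))

  # matching edges, two per similarity edge
  e_m <- NULL
  if (nrow(gs) > 0L) {
    e_m <- data.frame(
      pair = rep(seq_len(nrow(gs)), each = 2L),
      side = rep(c("t", "h"), times = nrow(gs)),
      vi = as.vector(rbind(unname(idxA[extremity(gs$gene_a, "t")]),
                           unname(idxA[extremity(gs$gene_a, "h")]))),
      vj = as.vector(rbind(unname(idxB[extremity(gs$gene_b, "t")]),
                           unname(idxB[extremity(gs$gene_b, "h")]))),
      weight = rep(gs$sigma, each = 2L))
  } else {
    e_m <- data.frame(pair = integer(), side = character(),
                      vi = integer(), vj = integer(), weight = numeric())
  }

  structure(list(A = A, B = B, S = gs,
                 A_work = A_w, B_work = B_w,
                 vertices = vertices, n_xa = nrow(va),
                 adj_partner = adjp,
                 e_a = e_a, e_s = e_s, e_m = e_m,
                 idxA = idxA, idxB = idxB),
            class = "ilp_model")
}

#' @export
print.ilp_model <- function(x, ...) {
  cat("FFDCJ distance ILP model:", nrow(x$vertices), "vertices (",
      x$n_xa, "in X_A ),", nrow(x$e_m), "matching edges,",
      length(x$e_a), "adjacency edges,",
      if (is.null(x$e_s)) 0L else nrow(x$e_s), "self edges\n")
  invisible(x)
}

#' Export an ILP model in LP file format
#'
#' Writes the model of [build_distance_ilp()] as a CPLEX-style LP file so
#' it can be handed to an external MILP solver. The objective uses the
#' scaling sum(x_e) - 1/2 sum(w_e x_e) - sum(z_i) over matching edges,
#' which evaluates to 2|M| - w(M) - (number of counted cycles); see the
#' package vignette for why this scaling, and not a coefficient 2 on the
#' first sum, matches the distance, and for the treatment of path
#' components.
#'
#' @param model an `"ilp_model"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
ilp_write_lp <- function(model, path) {
  stopifnot(inherits(model, "ilp_model"))
  k <- nrow(model$vertices)
  em <- model$e_m
  xm <- if (nrow(em)) paste0("x_m", seq_len(nrow(em))) else character()
  xa <- if (length(model$e_a)) paste0("x_a", seq_along(model$e_a)) else character()
  xs <- if (!is.null(model$e_s) && nrow(model$e_s)) {
    paste0("x_s", seq_len(nrow(model$e_s)))
  } else character()
  lines <- c("Minimize", paste0(" obj: ", paste(
    c(sprintf("%+.9g %s", 1 - em$weight / 2, xm),
      if (model$n_xa > 0L) sprintf("- z%d", seq_len(model$n_xa))),
    collapse = " ")))
  cons <- character()
  # (1) adjacency edges forced
  cons <- c(cons, sprintf(" adj%d: %s = 1", seq_along(xa), xa))
  # (2) one chosen E_m/E_s edge per vertex
  inc <- vector("list", k)
  if (nrow(em)) for (r in seq_len(nrow(em))) {
    inc[[em$vi[r]]] <- c(inc[[em$vi[r]]], xm[r])
    inc[[em$vj[r]]] <- c(inc[[em$vj[r]]], xm[r])
  }
  if (length(xs)) for (r in seq_len(nrow(model$e_s))) {
    for (v in model$e_s[r, ]) inc[[v]] <- c(inc[[v]], xs[r])
  }
  for (v in seq_len(k)) {
    if (length(inc[[v]])) {
      cons <- c(cons, sprintf(" deg%d: %s = 1", v,
                              paste(inc[[v]], collapse = " + ")))
    }
  }
  # (3) head/tail consistency per similarity edge
  if (nrow(em)) {
    for (p in unique(em$pair)) {
      rr <- which(em$pair == p)
      cons <- c(cons, sprintf(" cons%d: %s - %s = 0", p, xm[rr[1L]], xm[rr[2L]]))
    }
  }
  # (4) maximality: both endpoint self edges of a similarity edge not chosen
  if (nrow(model$S) > 0L && length(xs)) {
    sk <- paste(model$vertices$gene[model$e_s[, 1L]],
                model$vertices$genome[model$e_s[, 1L]])
    self_id <- stats::setNames(seq_along(sk), sk)
    for (p in seq_len(nrow(model$S))) {
      sa <- self_id[[paste(model$S$gene_a[p], "A")]]
      sb <- self_id[[paste(model$S$gene_b[p], "B")]]
      cons <- c(cons, sprintf(" maxl%d: %s + %s <= 1", p, xs[sa], xs[sb]))
    }
  }
  # (5) labels: adjacent vertices share the label (big-M via upper bound i)
  all_edges <- rbind(
    if (nrow(em)) cbind(em$vi, em$vj),
    if (length(model$e_a)) do.call(rbind, model$e_a),
    model$e_s)
  all_names <- c(xm, xa, xs)
  if (!is.null(all_edges) && nrow(all_edges)) {
    for (r in seq_len(nrow(all_edges))) {
      i <- all_edges[r, 1L]; j <- all_edges[r, 2L]; xe <- all_names[r]
      cons <- c(cons,
                sprintf(" lbl%da: y%d - y%d + %d %s <= %d", r, i, j, i, xe, i),
                sprintf(" lbl%db: y%d - y%d + %d %s <= %d", r, j, i, j, xe, j))
    }
  }
  # (6) counters restricted to X_A
  if (model$n_xa > 0L) {
    cons <- c(cons, sprintf(" cnt%d: %d z%d - y%d <= 0",
                            seq_len(model$n_xa), seq_len(model$n_xa),
                            seq_len(model$n_xa), seq_len(model$n_xa)))
  }
  bounds <- sprintf(" 0 <= y%d <= %d", seq_len(k), seq_len(k))
  bins <- c(xm, xa, xs, if (model$n_xa > 0L) paste0("z", seq_len(model$n_xa)))
  lines <- c(lines, "Subject To", cons, "Bounds", bounds,
             "Binaries", paste0(" ", paste(bins, collapse = " ")), "End")
  writeLines(lines, path)
  invisible(path)
}

# Objective of a complete assignment: walk H under the chosen edges and
# sum weighted component contributions. `partner_of[a_gene]` gives the
# matched similarity-edge row or NA (excised). Components without any
# matching edge (fully excised chromosome fragments) contribute nothing,
# matching the reduced-genome semantics.
ilp_leaf_objective <- function(model, msp, cross, wvec) {
  k <- nrow(model$vertices)
  adjp <- model$adj_partner
  visited <- logical(k)
  total <- 0
  eval_run <- function(start, cyclic) {
    v <- start
    km <- 0L
    wm <- 0
    repeat {
      visited[v] <<- TRUE
      u <- msp[v]            # the unique chosen E_m/E_s step
      if (cross[v]) {
        km <- km + 1L
        wm <- wm + wvec[v]
      }
      visited[u] <<- TRUE
      v <- adjp[u]
      if (v == 0L || (cyclic && v == start) || visited[v]) break
    }
    if (km == 0L) return(0)
    f <- 2 * km - wm
    if (cyclic) f / 2 - 1
    else if (km %% 2L == 1L) (f - 1) / 2
    else f / 2
  }
  telo <- which(adjp == 0L)
  for (v in telo) if (!visited[v]) total <- total + eval_run(v, FALSE)
  for (v in seq_len(k)) if (!visited[v]) total <- total + eval_run(v, TRUE)
  total
}

#' Solve the family-free DCJ distance ILP exactly
#'
#' An exact branch-and-bound solver specialized to the structure of the
#' model from [build_distance_ilp()]: it branches over the per-gene
#' choice "match along similarity edge e / excise" (the binary matching
#' and self-edge variables, with the head/tail consistency and degree
#' constraints applied implicitly), prunes with the admissible bound
#' sum(1 - sigma(e)) over decided matched pairs (each matched pair can
#' lower the objective by at most 1 through the components it enables),
#' enforces maximality at the leaves, and evaluates the exact objective
#' 2|M| - w(M) - c - i/2 by decomposing H directly - the closed-form
#' optimum of the label/counter variables, extended with the odd-path
#' term that the cycle counter alone cannot express. The reported
#' distance is always recomputed from the returned matching via
#' [dsigma()], never read off the raw objective.
#'
#' @param model an `"ilp_model"` from [build_distance_ilp()].
#' @param time_limit wall-clock limit in seconds (default 3600).
#' @param node_cap maximum number of search nodes.
#' @return An object of class `"ffdcj_solution"`: list with `matching`,
#'   `distance`, `objective_value`, `status` (`"optimal"` or
#'   `"feasible_time_limit"`), `gap` (0 when optimal) and `nodes`.
#' @export
solve_distance <- function(model, time_limit = 3600, node_cap = 2^22) {
  stopifnot(inherits(model, "ilp_model"))
  gs <- model$S
  k <- nrow(model$vertices)
  genesA <- intersect(gene_set(model$A_work), gs$gene_a)

  # baseline step map: everything excised (self edges)
  tpos <- stats::setNames(seq_len(k), paste(model$vertices$genome,
                                            model$vertices$label))
  vA <- function(lbl) unname(tpos[paste("A", lbl)])
  vB <- function(lbl) unname(tpos[paste("B", lbl)])
  base_msp <- integer(k)
  for (g in gene_set(model$A_work)) {
    i <- vA(extremity(g, "t")); j <- vA(extremity(g, "h"))
    base_msp[i] <- j; base_msp[j] <- i
  }
  for (g in gene_set(model$B_work)) {
    i <- vB(extremity(g, "t")); j <- vB(extremity(g, "h"))
    base_msp[i] <- j; base_msp[j] <- i
  }

  cand <- lapply(genesA, function(g) which(gs$gene_a == g))
  nA <- length(genesA)
  bt <- vapply(gs$gene_b, function(b) vB(extremity(b, "t")), integer(1))
  bh <- vapply(gs$gene_b, function(b) vB(extremity(b, "h")), integer(1))
  at <- vapply(gs$gene_a, function(a) vA(extremity(a, "t")), integer(1))
  ah <- vapply(gs$gene_a, function(a) vA(extremity(a, "h")), integer(1))

  best <- list(obj = Inf, sel = NULL)
  nodes <- 0L
  hit_limit <- FALSE
  t0 <- proc.time()[["elapsed"]]
  sel <- integer(nA)        # 0 = excise, else gs row
  used_b <- character()

  evaluate_leaf <- function() {
    sat_a <- genesA[sel > 0L]
    sat_b <- gs$gene_b[sel[sel > 0L]]
    if (nrow(gs) &&
        !all(gs$gene_a %in% sat_a | gs$gene_b %in% sat_b)) {
      return(invisible(NULL))  # not maximal
    }
    msp <- base_msp
    cross <- logical(k)
    wvec <- numeric(k)
    for (r in sel[sel > 0L]) {
      i1 <- at[r]; j1 <- bt[r]; i2 <- ah[r]; j2 <- bh[r]
      msp[i1] <- j1; msp[j1] <- i1; msp[i2] <- j2; msp[j2] <- i2
      cross[c(i1, j1, i2, j2)] <- TRUE
      wvec[c(i1, j1, i2, j2)] <- gs$sigma[r]
    }
    obj <- ilp_leaf_objective(model, msp, cross, wvec)
    if (obj < best$obj - 1e-12) best <<- list(obj = obj, sel = sel)
    invisible(NULL)
  }

  rec <- function(g, bound) {
    nodes <<- nodes + 1L
    if (hit_limit) return(invisible(NULL))
    if (nodes %% 512L == 0L &&
        (proc.time()[["elapsed"]] - t0 > time_limit || nodes > node_cap)) {
      hit_limit <<- TRUE
      return(invisible(NULL))
    }
    if (bound >= best$obj - 1e-12) return(invisible(NULL))
    if (g > nA) return(evaluate_leaf())
    for (r in cand[[g]]) {
      if (gs$gene_b[r] %in% used_b) next
      sel[g] <<- r
      used_b <<- c(used_b, gs$gene_b[r])
      rec(g + 1L, bound + 1 - gs$sigma[r])
      used_b <<- used_b[-length(used_b)]
      sel[g] <<- 0L
    }
    rec(g + 1L, bound)   # excise gene g
    invisible(NULL)
  }
  rec(1L, 0)

  sel_rows <- best$sel[best$sel > 0L]
  matching <- gs[sel_rows, , drop = FALSE]
  rownames(matching) <- NULL
  distance <- if (is.null(best$sel)) NA_real_ else {
    dsigma(reduce_genomes(model$A, model$B, matching))
  }
  status <- if (hit_limit) "feasible_time_limit" else "optimal"
  if (status == "optimal" && !is.null(best$sel) &&
      abs(distance - best$obj) > 1e-6) {
    stop("internal error: solver objective disagrees with recomputed d_sigma",
         call. = FALSE)
  }
  structure(list(matching = matching, distance = distance,
                 objective_value = best$obj, status = status,
                 gap = if (status == "optimal") 0 else NA_real_,
                 nodes = nodes),
            class = "ffdcj_solution")
}

#' @export
print.ffdcj_solution <- function(x, ...) {
  cat("FFDCJ solution:", x$status, " distance =", format(x$distance),
      " |M| =", nrow(x$matching), " nodes =", x$nodes, "\n")
  invisible(x)
}

#' Family-free DCJ distance via the ILP solver
#'
#' Convenience wrapper: builds the model with [build_distance_ilp()] and
#' solves it with [solve_distance()].
#'
#' @inheritParams build_distance_ilp
#' @param ... passed to [solve_distance()].
#' @return An `"ffdcj_solution"`.
#' @export
ffdcj_distance_ilp <- function(A, B, S, ...) {
  solve_distance(build_distance_ilp(A, B, S), ...)
}
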