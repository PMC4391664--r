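#' Hardness-gadget instance: maximum-weight matching is no approximation
#'
#' Builds the two unichromosomal linear genomes with 2k genes each in
#' alternating orientation, A = (1 -2 3 -4 ... (2k-1) -2k) and
#' B = (-(2k+1) (2k+2) ... -(4k-1) 4k), together with the similarity
#' table sigma(i, 2k+i) = 1 for all i and sigma(i, 2k+i+1) = 1 - epsilon
#' for odd i. The all-weight-1 matching M (size 2k) has d_sigma(M) = |M|,
#' while the all-(1-epsilon) matching M* (size k) has
#' d_sigma(M*) = epsilon |M*|, so their ratio is 2/epsilon: the unique
#' maximum-weight matching can be arbitrarily far from the optimum.
#'
#' @param k a positive integer (half the gene count per genome).
#' @param epsilon a number in \[0, 1).
#' @return list with genomes `A`, `B`, the `similarities` table, and the
#'   two distinguished matchings `M_heavy` (all weight-1 edges) and
#'   `M_star` (all weight-(1-epsilon) edges).
#' @export
counterexample_instance <- function(k, epsilon = 0.1) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == round(k),
            is.numeric(epsilon), length(epsilon) == 1L,
            epsilon >= 0, epsilon < 1)
  k <- as.integer(k)
  ia <- seq_len(2L * k)
  A <- genome("A", chromosome(paste0(ifelse(ia %% 2L == 0L, "-", ""), ia)))
  ib <- 2L * k + ia
  B <- genome("B", chromosome(paste0(ifelse(ia %% 2L == 1L, "-", ""), ib)))
  heavy <- data.frame(gene_a = as.character(ia),
                      gene_b = as.character(2L * k + ia),
                      sigma = 1)
  odd <- ia[ia %% 2L == 1L]
  star <- data.frame(gene_a = as.character(odd),
                     gene_b = as.character(2L * k + odd + 1L),
                     sigma = 1 - epsilon)
  S <- similarity_table(rbind(heavy, star), A, B)
  list(A = A, B = B, similarities = S,
       M_heavy = as_matching(heavy), M_star = as_matching(star))
}

#' Transform an exemplar-distance instance into a family-free instance
#'
#' The reduction map from the exemplar DCJ distance to the family-free
#' DCJ distance: gene occurrences of A are relabeled 1..|A| by position
#' and those of B by |A|+1..|A|+|B|, keeping orientations, and
#' sigma = 1 exactly for cross-genome pairs of occurrences from the same
#' family. Every family of B must also occur in A.
#'
#' @param A,B [genome()] objects over a common family alphabet; duplicates
#'   allowed.
#' @return list with relabeled genomes `A_f`, `B_f`, the unit-weight
#'   `similarities` table, and `families`, the occurrence bookkeeping
#'   (data.frames mapping new integer names to source families).
#' @export
exemplar_to_ff_instance <- function(A, B) {
  validate_genome(A, allow_duplicates = TRUE)
  validate_genome(B, allow_duplicates = TRUE)
  occA <- gene_occurrences(A)
  occB <- gene_occurrences(B)
  absent <- setdiff(occB$gene, occA$gene)
  if (length(absent)) {
    stop("family in B absent from A: ",
         paste(utils::head(absent, 3L), collapse = ", "), call. = FALSE)
  }
  nA <- nrow(occA)
  occA$new <- as.character(seq_len(nA))
  occB$new <- as.character(nA + seq_len(nrow(occB)))
  relabel <- function(G, occ) {
    chroms <- list()
    for (ci in seq_along(G$chromosomes)) {
      ch <- G$chromosomes[[ci]]
      nn <- occ$new[occ$chromosome == ci]
      chroms[[ci]] <- structure(list(genes = nn, signs = ch$signs,
                                     circular = ch$circular),
                                class = "chromosome")
    }
    genome(G$name, chroms)
  }
  A_f <- relabel(A, occA)
  B_f <- relabel(B, occB)
  pairs <- merge(occA[, c("gene", "new")], occB[, c("gene", "new")],
                 by = "gene", suffixes = c("_a", "_b"))
  S <- data.frame(gene_a = pairs$new_a, gene_b = pairs$new_b, sigma = 1)
  S <- S[order(as.integer(S$gene_a), as.integer(S$gene_b)), , drop = FALSE]
  rownames(S) <- NULL
  list(A_f = A_f, B_f = B_f,
       similarities = similarity_table(S, A_f, B_f),
       families = list(A = occA, B = occB))
}

#' Map a family-free matching back to exemplar genomes
#'
#' Inverse direction of the reduction: given a matching M of the
#' transformed instance, keep exactly the matched occurrences of the
#' source genomes (order and orientation preserved, original family
#' names restored).
#'
#' @param M a matching over the transformed instance of
#'   [exemplar_to_ff_instance()].
#' @param A,B the source genomes that were transformed.
#' @return list with exemplar genomes `A_x` and `B_x`.
#' @export
ff_matching_to_exemplar <- function(M, A, B) {
  M <- as_matching(M)
  inst <- exemplar_to_ff_instance(A, B)
  occA <- inst$families$A
  occB <- inst$families$B
  if (!all(M$gene_a %in% occA$new) || !all(M$gene_b %in% occB$new)) {
    stop("matching is not over the transformed instance of these genomes",
         call. = FALSE)
  }
  pick <- function(G, occ, keep_new) {
    chroms <- list()
    for (ci in seq_along(G$chromosomes)) {
      ch <- G$chromosomes[[ci]]
      sel <- occ$new[occ$chromosome == ci] %in% keep_new
      if (!any(sel)) next
      chroms[[length(chroms) + 1L]] <- structure(
        list(genes = ch$genes[sel], signs = ch$signs[sel],
             circular = ch$circular), class = "chromosome")
    }
    genome(G$name, chroms)
  }
  list(A_x = pick(A, occA, M$gene_a), B_x = pick(B, occB, M$gene_b))
}

#' Configuration for the rearrangement-pair simulator
#'
#' Bundles the generator parameters; see [simulate_pair()]. The preset
#' `r` in 1, 2, 5 scales the structural-event intensities the way a
#' 1x/2x/5x increase of duplication, loss and rearrangement rates scales
#' a pairwise comparison: with a per-gene, per-unit-time rearrangement
#' rate of 0.0025 and duplication/loss rates of 0.001 over a pairwise
#' divergence of 200 time units, the expected event counts per gene are
#' 0.5 r rearrangements and 0.2 r duplications/losses.
#'
#' @param n_genes number of genes in the ancestor genome.
#' @param n_chromosomes number of chromosomes.
#' @param topology `"linear"` or `"circular"`.
#' @param r rate multiplier preset (1, 2 or 5); sets the three event
#'   intensities below unless they are given explicitly.
#' @param n_rearrangements number of inversions/translocations applied.
#' @param dup_rate,loss_rate expected duplications/losses per genome
#'   (Poisson intensities).
#' @param weight_noise true-pair sigma is drawn as 1 - U(0, weight_noise).
#' @param spurious_edge_rate probability of a spurious similarity edge
#'   between an unrelated gene pair.
#' @param paralog_weight_range range of sigma for duplicate-induced
#'   paralog edges.
#' @param seed integer seed; the same configuration always yields the
#'   same instance.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 25, n_chromosomes = 1,
                              topology = c("linear", "circular"),
                              r = 1,
                              n_rearrangements = round(0.5 * r * n_genes),
                              dup_rate = 0.2 * r,
                              loss_rate = 0.2 * r,
                              weight_noise = 0.1,
                              spurious_edge_rate = 0.02,
                              paralog_weight_range = c(0.3, 0.9),
                              seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_genes >= 1, n_chromosomes >= 1, n_chromosomes <= n_genes,
            n_rearrangements >= 0, dup_rate >= 0, loss_rate >= 0,
            weight_noise >= 0, weight_noise < 1,
            spurious_edge_rate >= 0, spurious_edge_rate <= 1,
            length(paralog_weight_range) == 2L,
            paralog_weight_range[1] > 0, paralog_weight_range[2] < 1,
            diff(paralog_weight_range) >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 topology = topology,
                 n_rearrangements = as.integer(n_rearrangements),
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 weight_noise = weight_noise,
                 spurious_edge_rate = spurious_edge_rate,
                 paralog_weight_range = paralog_weight_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a diverged genome pair with a noisy similarity table
#'
#' Desk-scale emulation of a rearrangement-evolution experiment: genome B
#' is derived from a random ancestor A by random DCJ rearrangements
#' (inversions, and translocations when several linear chromosomes
#' exist), followed by gene duplications and losses; the similarity
#' table assigns high weights (1 - U(0, weight_noise)) to true
#' orthologous pairs, intermediate weights to duplicate-induced paralog
#' edges, and sprinkles spurious edges between unrelated genes. The
#' ground-truth orthology matching is returned alongside. Reproducible
#' from the seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with genomes `A` and `B`, the `similarities` table, and
#'   `truth`, the ground-truth matching.
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    fams <- paste0("g", seq_len(n))
    split_sizes <- function(n, k) {
      cuts <- sort(sample(seq_len(n - 1L), k - 1L))
      diff(c(0L, cuts, n))
    }
    sizes <- if (cfg$n_chromosomes == 1L) n else
      split_sizes(n, cfg$n_chromosomes)
    idx <- split(seq_len(n), rep(seq_along(sizes), sizes))
    A <- genome("A", lapply(idx, function(ii) {
      structure(list(genes = fams[ii],
                     signs = sample(c(-1L, 1L), length(ii), replace = TRUE),
                     circular = cfg$topology == "circular"),
                class = "chromosome")
    }))
    # B starts as a copy of A; each occurrence remembers its family
    chromsB <- lapply(A$chromosomes, function(ch) {
      list(fam = ch$genes, signs = ch$signs, circular = ch$circular)
    })

    invert <- function(ch) {
      m <- length(ch$fam)
      if (m < 2L) return(ch)
      ij <- sort(sample(m, 2L))
      seg <- ij[1L]:ij[2L]
      ch$fam[seg] <- rev(ch$fam[seg])
      ch$signs[seg] <- -rev(ch$signs[seg])
      ch
    }
    translocate <- function(c1, c2) {
      # exchange suffixes of two linear chromosomes
      p1 <- sample(0:length(c1$fam), 1L)
      p2 <- sample(0:length(c2$fam), 1L)
      h1 <- seq_len(p1)
      h2 <- seq_len(p2)
      new1 <- list(fam = c(c1$fam[h1], c2$fam[setdiff(seq_along(c2$fam), h2)]),
                   signs = c(c1$signs[h1],
                             c2$signs[setdiff(seq_along(c2$fam), h2)]),
                   circular = FALSE)
      new2 <- list(fam = c(c2$fam[h2], c1$fam[setdiff(seq_along(c1$fam), h1)]),
                   signs = c(c2$signs[h2],
                             c1$signs[setdiff(seq_along(c1$fam), h1)]),
                   circular = FALSE)
      list(new1, new2)
    }
    for (step in seq_len(cfg$n_rearrangements)) {
      linear <- which(!vapply(chromsB, `[[`, logical(1), "circular"))
      can_transloc <- length(linear) >= 2L
      if (can_transloc && stats::runif(1) < 0.3) {
        pair <- sample(linear, 2L)
        res <- translocate(chromsB[[pair[1L]]], chromsB[[pair[2L]]])
        res <- Filter(function(ch) length(ch$fam) > 0L, res)
        chromsB <- c(chromsB[-pair], res)
      } else {
        ci <- sample(seq_along(chromsB), 1L)
        chromsB[[ci]] <- invert(chromsB[[ci]])
      }
    }
    n_dup <- stats::rpois(1L, cfg$dup_rate)
    dup_fams <- character()
    for (d in seq_len(n_dup)) {
      ci <- sample(seq_along(chromsB), 1L)
      src <- chromsB[[ci]]
      pos <- sample(length(src$fam), 1L)
      ti <- sample(seq_along(chromsB), 1L)
      tgt <- chromsB[[ti]]
      at <- sample(0:length(tgt$fam), 1L)
      head_ <- seq_len(at)
      chromsB[[ti]]$fam <- append(tgt$fam, src$fam[pos], after = at)
      chromsB[[ti]]$signs <- append(tgt$signs, src$signs[pos], after = at)
      dup_fams <- c(dup_fams, src$fam[pos])
    }
    n_loss <- stats::rpois(1L, cfg$loss_rate)
    for (d in seq_len(n_loss)) {
      tot <- sum(vapply(chromsB, function(ch) length(ch$fam), integer(1)))
      if (tot <= 1L) break
      ci <- sample(rep(seq_along(chromsB),
                       vapply(chromsB, function(ch) length(ch$fam),
                              integer(1))), 1L)
      pos <- sample(length(chromsB[[ci]]$fam), 1L)
      chromsB[[ci]]$fam <- chromsB[[ci]]$fam[-pos]
      chromsB[[ci]]$signs <- chromsB[[ci]]$signs[-pos]
    }
    chromsB <- Filter(function(ch) length(ch$fam) > 0L, chromsB)

    # name B occurrences uniquely; the first surviving copy of a family
    # is its ortholog, later copies are paralogs
    occ_fam <- unlist(lapply(chromsB, `[[`, "fam"), use.names = FALSE)
    bname <- paste0("h", seq_along(occ_fam))
    primary <- !duplicated(occ_fam)
    off <- 0L
    B <- genome("B", lapply(chromsB, function(ch) {
      m <- length(ch$fam)
      nm <- bname[off + seq_len(m)]
      off <<- off + m
      structure(list(genes = nm, signs = ch$signs, circular = ch$circular),
                class = "chromosome")
    }))

    sim <- data.frame(gene_a = character(), gene_b = character(),
                      sigma = numeric())
    truth <- sim
    for (i in seq_along(occ_fam)) {
      fam <- occ_fam[i]
      if (primary[i]) {
        s <- if (cfg$weight_noise > 0) {
          1 - stats::runif(1L, 0, cfg$weight_noise)
        } else 1
        sim <- rbind(sim, data.frame(gene_a = fam, gene_b = bname[i],
                                     sigma = s))
        truth <- rbind(truth, data.frame(gene_a = fam, gene_b = bname[i],
                                         sigma = s))
      } else {
        s <- stats::runif(1L, cfg$paralog_weight_range[1L],
                          cfg$paralog_weight_range[2L])
        sim <- rbind(sim, data.frame(gene_a = fam, gene_b = bname[i],
                                     sigma = s))
      }
    }
    if (cfg$spurious_edge_rate > 0) {
      have <- paste(sim$gene_a, sim$gene_b, sep = "\r")
      for (fam in fams) {
        for (i in seq_along(occ_fam)) {
          if (occ_fam[i] == fam) next
          if (paste(fam, bname[i], sep = "\r") %in% have) next
          if (stats::runif(1L) < cfg$spurious_edge_rate) {
            sim <- rbind(sim, data.frame(
              gene_a = fam, gene_b = bname[i],
              sigma = stats::runif(1L, cfg$paralog_weight_range[1L],
                                   cfg$paralog_weight_range[2L])))
          }
        }
      }
    }
    list(A = A, B = B,
         similarities = similarity_table(sim, A, B),
         truth = as_matching(truth))
  })
}

#' Worked-example fixtures
#'
#' Small named instances used throughout the documentation and tests:
#' `"fig1"`, two unichromosomal linear four-gene genomes whose adjacency
#' graph has one cycle and two odd paths (DCJ distance 2); `"fig2"`, the
#' five/six-gene pair used for the weighted worked examples, carrying
#' matching-level aggregates only (per-edge weights are free; any
#' size-5 matching with weight 2.7 whose weighted adjacency graph has
#' three cycles and two odd paths gives d_sigma = 3.3, and weight 3.9
#' with two cycles and two odd paths gives 3.1); `"fig4"`, the
#' exemplar-reduction gadget with its unit-weight similarity graph and
#' highlighted matching; `"fig5_k3"`, the counterexample gadget at k = 3.
#'
#' @param name one of `"fig1"`, `"fig2"`, `"fig4"`, `"fig5_k3"`.
#' @param epsilon epsilon for `"fig5_k3"` (default 0.1).
#' @return A list; contents depend on the fixture.
#' @export
load_fixture <- function(name, epsilon = 0.1) {
  switch(
    name,
    fig1 = {
      g <- parse_genomes(">A\n-1 3 4 2 |\n>B\n-2 1 4 3 |")
      list(A = g$A, B = g$B, distance = 2, n = 4, cycles = 1, odd_paths = 2)
    },
    fig2 = {
      g <- parse_genomes(">A\n1 2 3 4 5 |\n>B\n6 -7 -8 -9 10 11 |")
      list(A = g$A, B = g$B,
           M1 = list(size = 5, weight = 2.7, cycles = 3, odd_paths = 2,
                     dsigma = 3.3),
           M2 = list(size = 5, weight = 3.9, cycles = 2, odd_paths = 2,
                     dsigma = 3.1))
    },
    fig4 = {
      g <- parse_genomes(">A\na c -b d |\n>B\n-c d a c b -b |")
      inst <- exemplar_to_ff_instance(g$A, g$B)
      M <- data.frame(gene_a = c("1", "2", "3", "4"),
                      gene_b = c("7", "8", "10", "6"), sigma = 1)
      c(list(A = g$A, B = g$B, matching = as_matching(M)), inst)
    },
    fig5_k3 = counterexample_instance(3L, epsilon),
    stop("unknown fixture '", name, "'", call. = FALSE)
  )
}
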