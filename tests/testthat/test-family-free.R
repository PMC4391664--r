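fig4 <- load_fixture("fig4")

test_that("the gene similarity graph mirrors the table and the gadget degrees", {
  G <- build_gs_graph(fig4$A_f, fig4$B_f, fig4$similarities)
  expect_equal(nrow(G$edges), 6L)
  degA <- table(factor(G$edges$gene_a, levels = G$genes_a))
  expect_equal(as.integer(degA), c(1L, 2L, 2L, 1L))
  expect_true(all(table(G$edges$gene_b) == 1L))
  # empty table -> edgeless graph
  A <- genome("A", chromosome("x"))
  B <- genome("B", chromosome("y"))
  G0 <- build_gs_graph(A, B, data.frame(gene_a = character(),
                                        gene_b = character(),
                                        sigma = numeric()))
  expect_equal(nrow(G0$edges), 0L)
})

test_that("maximality of matchings is detected", {
  A <- genome("A", chromosome("x"))
  B <- genome("B", chromosome("y"))
  G0 <- build_gs_graph(A, B, data.frame(gene_a = character(),
                                        gene_b = character(),
                                        sigma = numeric()))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      sigma = numeric())
  expect_true(is_maximal_matching(G0, empty))
  G4 <- build_gs_graph(fig4$A_f, fig4$B_f, fig4$similarities)
  expect_false(is_maximal_matching(G4, empty))
  expect_true(is_maximal_matching(G4, fig4$matching))
  notM <- data.frame(gene_a = c("2", "2"), gene_b = c("5", "8"),
                     sigma = c(1, 1))
  expect_error(as_matching(notM), "repeated endpoint")
})

test_that("reduced genomes excise unsaturated genes and relabel the rest", {
  R <- reduce_genomes(fig4$A_f, fig4$B_f, fig4$matching)
  expect_setequal(gene_set(R$A), as.character(1:4))
  expect_setequal(gene_set(R$B), as.character(1:4))
  # B had 6 genes; the two unsaturated ones are gone
  expect_equal(n_genes(R$B), 4L)
  # orientation preserved: gene labeled from -b stays reversed
  occ <- gene_occurrences(R$A)
  expect_equal(occ$sign, c(1L, 1L, -1L, 1L))
  # empty matching -> empty genomes
  R0 <- reduce_genomes(fig4$A_f, fig4$B_f,
                       data.frame(gene_a = character(),
                                  gene_b = character(), sigma = numeric()))
  expect_equal(n_genes(R0$A), 0L)
  expect_equal(dsigma(R0), 0)
  # a fully unsaturated circular chromosome disappears
  Ac <- genome("A", list(chromosome("a1"), chromosome("a2", circular = TRUE)))
  Bc <- genome("B", chromosome("b1"))
  R1 <- reduce_genomes(Ac, Bc, data.frame(gene_a = "a1", gene_b = "b1",
                                          sigma = 1))
  expect_length(R1$A$chromosomes, 1L)
})

test_that("weighted adjacency graph carries sigma on both extremity edges", {
  R <- reduce_genomes(fig4$A_f, fig4$B_f, fig4$matching)
  w <- build_weighted_adjacency_graph(R)
  expect_equal(sum(w$edges$weight), 2 * matching_weight(R$matching))
  # each gene's two extremity edges have equal weight
  gene_of <- sub(":(t|h)$", "", w$edges$extremity)
  for (g in unique(gene_of)) {
    expect_equal(length(unique(w$edges$weight[gene_of == g])), 1L)
  }
})

test_that("weighted component contributions evaluate the 2|C|-w(C) table", {
  expect_equal(weighted_component_contribution("cycle", 2L, 2), 0)
  expect_equal(weighted_component_contribution("odd_path", 1L, 0.5), 0.25)
  expect_equal(weighted_component_contribution("cycle", 2L, 1.0), 0.5)
  expect_equal(weighted_component_contribution("even_path", 2L, 2), 1)
  # reduces to the unweighted contribution when w(C) = |C|
  for (kind in c("cycle", "odd_path", "even_path")) {
    len <- if (kind == "odd_path") 3L else 4L
    expect_equal(weighted_component_contribution(kind, len, len),
                 component_contribution(kind, len))
  }
})

test_that("s_sigma normalizes component weights by kind", {
  # identical circular single-gene genomes, sigma 1: one cycle, w = 2, |C| = 2
  A <- genome("A", chromosome("a", circular = TRUE))
  B <- genome("B", chromosome("b", circular = TRUE))
  R <- reduce_genomes(A, B, data.frame(gene_a = "a", gene_b = "b", sigma = 1))
  expect_equal(ssigma(R), 1)
  # linear single-gene pair, sigma 1: two odd paths of length 1 -> 1/2 + 1/2
  Al <- genome("A", chromosome("a"))
  Bl <- genome("B", chromosome("b"))
  Rl <- reduce_genomes(Al, Bl, data.frame(gene_a = "a", gene_b = "b",
                                          sigma = 1))
  expect_equal(ssigma(Rl), 1)
})

test_that("F_alpha interpolates between matching weight and s_sigma", {
  A <- genome("A", chromosome("a", circular = TRUE))
  B <- genome("B", chromosome("b", circular = TRUE))
  R <- reduce_genomes(A, B, data.frame(gene_a = "a", gene_b = "b",
                                       sigma = 0.8))
  expect_equal(f_alpha(R, 0), matching_weight(R$matching))
  expect_equal(f_alpha(R, 1), ssigma(R))
  expect_equal(f_alpha(R, 0.5), 0.5 * ssigma(R) + 0.5 * 0.8)
  expect_error(f_alpha(R, 1.2), "alpha")
})

test_that("d_sigma identities hold on random instances", {
  set.seed(303)
  for (rep in 1:100) {
    inst <- rand_ff_instance()
    G <- build_gs_graph(inst$A, inst$B, inst$S)
    Ms <- enumerate_maximal_matchings(G)
    M <- Ms[[sample(length(Ms), 1L)]]
    R <- reduce_genomes(inst$A, inst$B, M)
    comps <- decompose_components(build_weighted_adjacency_graph(R))
    m <- nrow(M)
    wM <- matching_weight(M)
    # total weight of the weighted adjacency graph is twice w(M)
    if (m > 0) {
      expect_equal(sum(comps$weight), 2 * wM, tolerance = 1e-9)
    }
    # component-sum route equals d_DCJ(A^M, B^M) + |M| - w(M)
    d <- dsigma(R)
    expect_equal(d, dcj_distance(R$A, R$B) + m - wM, tolerance = 1e-9)
    expect_gte(d, -1e-12)
    # component lengths partition the 2|M| extremity edges
    expect_equal(sum(comps$length), 2L * m)
    # with all weights forced to 1, d_sigma collapses to d_DCJ
    M1 <- M
    M1$sigma <- 1
    R1 <- reduce_genomes(inst$A, inst$B, M1)
    expect_equal(dsigma(R1), dcj_distance(R1$A, R1$B), tolerance = 1e-9)
    # lowering one matched weight by delta raises d_sigma by exactly delta
    if (m > 0) {
      delta <- 0.01
      M2 <- M
      M2$sigma[1L] <- M2$sigma[1L] - delta
      if (M2$sigma[1L] > 0) {
        expect_equal(dsigma(reduce_genomes(inst$A, inst$B, M2)), d + delta,
                     tolerance = 1e-9)
      }
    }
  }
})
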