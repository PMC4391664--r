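test_that("counterexample gadget has the stated structure and matchings", {
  ce <- counterexample_instance(3L, 0.1)
  expect_equal(n_genes(ce$A), 6L)
  expect_equal(n_genes(ce$B), 6L)
  expect_equal(nrow(ce$similarities), 9L)
  expect_equal(sum(ce$similarities$sigma == 1), 6L)
  expect_equal(sum(abs(ce$similarities$sigma - 0.9) < 1e-12), 3L)
  # alternating orientations, A starting forward, B starting reverse
  expect_equal(ce$A$chromosomes[[1L]]$signs, rep(c(1L, -1L), 3L))
  expect_equal(ce$B$chromosomes[[1L]]$signs, rep(c(-1L, 1L), 3L))
  G <- build_gs_graph(ce$A, ce$B, ce$similarities)
  expect_true(is_maximal_matching(G, ce$M_heavy))
  expect_true(is_maximal_matching(G, ce$M_star))
  expect_equal(nrow(ce$M_heavy), 2L * nrow(ce$M_star))
})

test_that("heavy and light gadget matchings have the predicted censuses and ratio", {
  for (k in 1:3) {
    for (eps in c(0.5, 0.1, 0.01)) {
      ce <- counterexample_instance(k, eps)
      Rh <- reduce_genomes(ce$A, ce$B, ce$M_heavy)
      ch <- decompose_components(build_weighted_adjacency_graph(Rh))
      # heavy matching: two even paths, no cycles or odd paths
      expect_equal(sum(ch$kind == "even_path"), 2L)
      expect_equal(sum(ch$kind != "even_path"), 0L)
      dh <- dsigma(Rh)
      expect_equal(dh, nrow(ce$M_heavy), tolerance = 1e-12)
      # light matching: |M*| - 1 cycles and two odd paths, d = eps |M*|
      Rs <- reduce_genomes(ce$A, ce$B, ce$M_star)
      cs <- decompose_components(build_weighted_adjacency_graph(Rs))
      expect_equal(sum(cs$kind == "cycle"), nrow(ce$M_star) - 1L)
      expect_equal(sum(cs$kind == "odd_path"), 2L)
      ds <- dsigma(Rs)
      expect_equal(ds, eps * nrow(ce$M_star), tolerance = 1e-12)
      expect_equal(dh / ds, 2 / eps, tolerance = 1e-9)
    }
  }
})

test_that("exemplar-to-family-free transform relabels and sets unit weights", {
  g <- parse_genomes(">A\na c -b d |\n>B\n-c d a c b -b |")
  inst <- exemplar_to_ff_instance(g$A, g$B)
  expect_setequal(gene_set(inst$A_f), as.character(1:4))
  expect_setequal(gene_set(inst$B_f), as.character(5:10))
  expect_true(all(inst$similarities$sigma == 1))
  expect_equal(nrow(inst$similarities), 6L)
  # orientations preserved
  expect_equal(inst$A_f$chromosomes[[1L]]$signs, g$A$chromosomes[[1L]]$signs)
  # duplicate-free A = B -> perfect matching graph, distance 0
  A <- genome("A", chromosome(c("x", "y")))
  inst2 <- exemplar_to_ff_instance(A, genome("B", chromosome(c("x", "y"))))
  expect_equal(nrow(inst2$similarities), 2L)
  expect_equal(ffdcj_distance_bruteforce(inst2$A_f, inst2$B_f,
                                         inst2$similarities)$distance, 0)
  # one family, 1 copy in A, 2 in B -> two edges sharing the A gene
  inst3 <- exemplar_to_ff_instance(genome("A", chromosome("x")),
                                   genome("B", chromosome(c("x", "x"))))
  expect_equal(nrow(inst3$similarities), 2L)
  expect_equal(length(unique(inst3$similarities$gene_a)), 1L)
  expect_error(exemplar_to_ff_instance(genome("A", chromosome("x")),
                                       genome("B", chromosome("z"))),
               "absent from A")
})

test_that("family-free matchings map back to exemplar genomes", {
  fig4 <- load_fixture("fig4")
  ex <- ff_matching_to_exemplar(fig4$matching, fig4$A, fig4$B)
  expect_true(genomes_equal(ex$A_x, parse_genomes(">X\na c -b d |")$X))
  expect_true(genomes_equal(ex$B_x, parse_genomes(">X\nd a c -b |")$X))
  # d_DCJ of the mapped exemplars equals d_sigma of the matching
  d_ex <- dcj_distance(ex$A_x, ex$B_x)
  d_ff <- dsigma(reduce_genomes(fig4$A_f, fig4$B_f, fig4$matching))
  expect_equal(d_ex, d_ff)
  # empty matching -> empty genomes
  e <- ff_matching_to_exemplar(data.frame(gene_a = character(),
                                          gene_b = character(),
                                          sigma = numeric()),
                               fig4$A, fig4$B)
  expect_equal(n_genes(e$A_x), 0L)
})

test_that("the simulator is seed-deterministic and neutral without events", {
  cfg0 <- simulation_config(n_genes = 6, n_rearrangements = 0, dup_rate = 0,
                            loss_rate = 0, weight_noise = 0,
                            spurious_edge_rate = 0, seed = 3L)
  p <- simulate_pair(cfg0)
  expect_identical(p, simulate_pair(cfg0))
  expect_equal(ffdcj_distance_bruteforce(p$A, p$B,
                                         p$similarities)$distance, 0)
  expect_true(all(p$similarities$sigma == 1))
  # rates and weights stay in range with all event types active
  cfg <- simulation_config(n_genes = 12, n_chromosomes = 2, r = 5, seed = 8L)
  q <- simulate_pair(cfg)
  expect_true(all(q$similarities$sigma > 0 & q$similarities$sigma <= 1))
  G <- build_gs_graph(q$A, q$B, q$similarities)
  expect_silent(as_matching(q$truth, G))
})

test_that("the optimal matching recovers the ground truth under mild noise", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- simulation_config(n_genes = 6, n_rearrangements = 2,
                             dup_rate = 0, loss_rate = 0, seed = s)
    p <- simulate_pair(cfg)
    bf <- ffdcj_distance_bruteforce(p$A, p$B, p$similarities)
    if (matching_key(bf$matching) == matching_key(p$truth)) hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of 50 replicates
})

test_that("fixtures load with their documented content", {
  f1 <- load_fixture("fig1")
  expect_equal(dcj_distance(f1$A, f1$B), f1$distance)
  f2 <- load_fixture("fig2")
  expect_equal(n_genes(f2$A), 5L)
  expect_equal(n_genes(f2$B), 6L)
  expect_equal(f2$M1$weight + f2$M2$weight, 6.6)
  f5 <- load_fixture("fig5_k3")
  expect_equal(nrow(f5$similarities), 9L)
  expect_error(load_fixture("nope"), "unknown fixture")
})
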