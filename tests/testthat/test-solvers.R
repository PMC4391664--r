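test_that("maximal matchings are enumerated exactly once each", {
  A <- genome("A", chromosome(c("a1", "a2")))
  B <- genome("B", chromosome(c("b1", "b2")))
  one <- build_gs_graph(A, B, data.frame(gene_a = "a1", gene_b = "b1",
                                         sigma = 1))
  expect_length(enumerate_maximal_matchings(one), 1L)
  # path a1 - b1 - a2: two maximal matchings
  path <- build_gs_graph(A, B, data.frame(gene_a = c("a1", "a2"),
                                          gene_b = c("b1", "b1"),
                                          sigma = c(1, 1)))
  expect_length(enumerate_maximal_matchings(path), 2L)
  # edgeless graph: exactly the empty matching
  none <- build_gs_graph(A, B, data.frame(gene_a = character(),
                                          gene_b = character(),
                                          sigma = numeric()))
  ms <- enumerate_maximal_matchings(none)
  expect_length(ms, 1L)
  expect_equal(nrow(ms[[1L]]), 0L)
  # every enumerated matching is maximal; none repeats
  set.seed(404)
  for (rep in 1:20) {
    inst <- rand_ff_instance()
    G <- build_gs_graph(inst$A, inst$B, inst$S)
    Ms <- enumerate_maximal_matchings(G)
    keys <- vapply(Ms, matching_key, character(1))
    expect_false(anyDuplicated(keys) > 0L)
    for (M in Ms) expect_true(is_maximal_matching(G, M))
  }
  expect_error(enumerate_maximal_matchings(path, cap = 2L), "cap exceeded")
})

test_that("brute-force distance finds the maximal-matching optimum", {
  fig4 <- load_fixture("fig4")
  bf <- ffdcj_distance_bruteforce(fig4$A_f, fig4$B_f, fig4$similarities)
  ex <- exemplar_dcj_bruteforce(fig4$A, fig4$B)
  expect_equal(bf$distance, ex$distance)
  # no edges -> empty matching, distance 0
  A <- genome("A", chromosome("x"))
  B <- genome("B", chromosome("y"))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      sigma = numeric())
  r <- ffdcj_distance_bruteforce(A, B, empty)
  expect_equal(r$distance, 0)
  expect_equal(nrow(r$matching), 0L)
  # gadget: the optimum is at most the value of the light matching
  ce <- counterexample_instance(2L, 0.25)
  opt <- ffdcj_distance_bruteforce(ce$A, ce$B, ce$similarities)
  expect_lte(opt$distance, 0.25 * nrow(ce$M_star) + 1e-12)
})

test_that("brute-force similarity finds the maximal-matching optimum", {
  A <- genome("A", chromosome("a"))
  B <- genome("B", chromosome("b"))
  r <- ffdcj_similarity_bruteforce(A, B, data.frame(gene_a = "a",
                                                    gene_b = "b", sigma = 1))
  expect_equal(r$similarity, 1)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      sigma = numeric())
  expect_equal(ffdcj_similarity_bruteforce(A, B, empty)$similarity, 0)
})

test_that("exemplar brute force handles duplicates and degenerate cases", {
  # worked gadget genomes: optimum 2, four exemplar pairs
  g <- parse_genomes(">A\na c -b d |\n>B\n-c d a c b -b |")
  r <- exemplar_dcj_bruteforce(g$A, g$B)
  expect_equal(r$n_pairs, 4)
  expect_equal(r$distance, 2)
  # the optimum is no worse than the hand exemplar pair (d a c -b)
  hand <- dcj_distance(g$A, parse_genomes(">Bx\nd a c -b |")$Bx)
  expect_lte(r$distance, hand)
  # identical duplicate-free genomes
  A <- genome("A", chromosome(c("x", "y")))
  expect_equal(exemplar_dcj_bruteforce(A, A)$distance, 0)
  # 2 copies in B, 1 in A: two exemplar pairs
  B2 <- genome("B", chromosome(c("x", "y", "x")))
  expect_equal(exemplar_dcj_bruteforce(A, B2)$n_pairs, 2)
  # family missing from one genome
  expect_error(exemplar_dcj_bruteforce(A, genome("B", chromosome("x"))),
               "family absent")
})

test_that("the ILP model has the prescribed shape", {
  fig4 <- load_fixture("fig4")
  model <- build_distance_ilp(fig4$A_f, fig4$B_f, fig4$similarities)
  # two matching edges per similarity edge
  expect_equal(nrow(model$e_m), 2L * nrow(fig4$similarities))
  expect_equal(unname(table(model$e_m$pair)), rep(2L, 6L),
               ignore_attr = TRUE)
  # all X_A vertices come before X_B
  expect_equal(model$vertices$genome,
               rep(c("A", "B"), c(model$n_xa,
                                  nrow(model$vertices) - model$n_xa)))
  # one self edge per gene kept
  expect_equal(nrow(model$e_s),
               n_genes(model$A_work) + n_genes(model$B_work))
  # LP export is syntactically complete
  lp <- tempfile(fileext = ".lp")
  ilp_write_lp(model, lp)
  txt <- readLines(lp)
  expect_true(any(grepl("^Minimize$", txt)))
  expect_true(any(grepl("^Subject To$", txt)))
  expect_true(any(grepl("maxl", txt)))  # maximality constraints present
  expect_true(any(grepl("cnt", txt)))   # cycle-counter constraints present
  expect_identical(txt[length(txt)], "End")
})

test_that("the ILP solver matches the brute-force oracle on random instances", {
  set.seed(505)
  for (rep in 1:60) {
    inst <- rand_ff_instance()
    bf <- ffdcj_distance_bruteforce(inst$A, inst$B, inst$S)
    sol <- ffdcj_distance_ilp(inst$A, inst$B, inst$S)
    expect_equal(sol$distance, bf$distance, tolerance = 1e-9)
    expect_identical(sol$status, "optimal")
    G <- build_gs_graph(inst$A, inst$B, inst$S)
    expect_true(is_maximal_matching(G, sol$matching))
  }
})

test_that("ILP distance equals the family-based distance on unit-weight instances", {
  set.seed(606)
  for (rep in 1:20) {
    p <- rand_fb_pair(max_genes = 6L)
    inst <- exemplar_to_ff_instance(p$A, p$B)
    sol <- ffdcj_distance_ilp(inst$A_f, inst$B_f, inst$similarities)
    expect_equal(sol$distance, dcj_distance(p$A, p$B), tolerance = 1e-9)
  }
})

test_that("empty similarity graphs solve to zero distance", {
  A <- genome("A", chromosome("x"))
  B <- genome("B", chromosome("y"))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      sigma = numeric())
  sol <- ffdcj_distance_ilp(A, B, empty)
  expect_equal(sol$distance, 0)
  expect_equal(nrow(sol$matching), 0L)
  expect_identical(sol$status, "optimal")
})
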