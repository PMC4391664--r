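# Shared random-instance builders for property-style tests.

# duplicate-free genome with 1-2 chromosomes of random topology
rand_genome <- function(name, genes) {
  n <- length(genes)
  nchr <- sample(seq_len(min(2L, n)), 1L)
  sizes <- if (nchr == 1L) n else {
    c1 <- sample(seq_len(n - 1L), 1L)
    c(c1, n - c1)
  }
  idx <- split(genes, rep(seq_along(sizes), sizes))
  genome(name, lapply(idx, function(g) {
    structure(list(genes = g,
                   signs = sample(c(-1L, 1L), length(g), replace = TRUE),
                   circular = sample(c(TRUE, FALSE), 1L)),
              class = "chromosome")
  }))
}

# family-free instance: disjoint gene names, random similarity edges
rand_ff_instance <- function(max_genes = 6L, max_edges = 12L) {
  na <- sample(2:max_genes, 1L)
  nb <- sample(2:max_genes, 1L)
  A <- rand_genome("A", paste0("a", seq_len(na)))
  B <- rand_genome("B", paste0("b", seq_len(nb)))
  pairs <- expand.grid(gene_a = gene_set(A), gene_b = gene_set(B),
                       stringsAsFactors = FALSE)
  ne <- sample(seq_len(max_edges), 1L)
  pairs <- pairs[sample(nrow(pairs), min(ne, nrow(pairs))), , drop = FALSE]
  pairs$sigma <- round(stats::runif(nrow(pairs), 0.05, 1), 3)
  list(A = A, B = B, S = similarity_table(pairs, A, B))
}

# duplicate-free pair over the same gene set (family-based setting)
rand_fb_pair <- function(max_genes = 7L) {
  n <- sample(2:max_genes, 1L)
  genes <- paste0("g", seq_len(n))
  list(A = rand_genome("A", sample(genes)),
       B = rand_genome("B", sample(genes)))
}

# (1,2)-exemplar instance: A duplicate-free, B with 1-2 copies per family
rand_12_instance <- function(max_families = 5L, circular = FALSE) {
  nf <- sample(2:max_families, 1L)
  fams <- letters[seq_len(nf)]
  A <- genome("A", structure(
    list(genes = sample(fams),
         signs = sample(c(-1L, 1L), nf, replace = TRUE),
         circular = circular), class = "chromosome"))
  copies <- unlist(lapply(fams, function(f) rep(f, sample(1:2, 1L))))
  B <- genome("B", structure(
    list(genes = sample(copies),
         signs = sample(c(-1L, 1L), length(copies), replace = TRUE),
         circular = circular), class = "chromosome"))
  list(A = A, B = B)
}

matching_key <- function(M) {
  paste(sort(paste(M$gene_a, M$gene_b)), collapse = ";")
}
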