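# ffdcj — family-free DCJ distance and similarity

`ffdcj` compares two genomes under the double-cut-and-join (DCJ)
rearrangement model **without prior gene family assignment**. It is aimed
at comparative-genomics researchers who have two signed gene orders and a
table of pairwise normalized gene similarities σ(a, b) ∈ (0, 1] — e.g.
normalized alignment scores — and want rearrangement-aware distance or
similarity measures, exact optima on small instances, or an exported ILP
model for industrial solvers on large ones.

## The measures

For duplication-free genomes with equal content, the classical DCJ
distance comes from the adjacency graph AG(A, B):

    d_DCJ(A, B) = n − c − i/2

(n genes, c cycles, i odd paths). In the family-free setting, a matching
M of the weighted bipartite *gene similarity graph* selects a tentative
orthology; unsaturated genes are excised, matched pairs are co-labeled,
and the *weighted adjacency graph* of the reduced genomes yields

    d_σ(A^M, B^M) = Σ_C d_σ(C) = d_DCJ(A^M, B^M) + |M| − w(M),

where each component contributes through f(C) = 2|C| − w(C). The
family-free DCJ distance minimizes d_σ — and the similarity s_σ
(component weights normalized by |C|, |C|+1 or |C|+2) maximizes — over
all **maximal** matchings. Both problems are hard; the package provides
brute-force reference solvers, an exact branch-and-bound solver for the
ILP formulation of the distance, an LP-format exporter, the hardness
gadgets, and a small rearrangement simulator with ground-truth orthology.

## Worked example

The classic gadget pair A = (∘ a c −b d ∘), B = (∘ −c d a c b −b ∘) —
one genome duplication-free, the other with families c and b twice —
transformed to a family-free instance with unit similarities:

```r
library(ffdcj)
g <- parse_genomes(">A\na c -b d |\n>B\n-c d a c b -b |")
inst <- exemplar_to_ff_instance(g$A, g$B)
sol <- ffdcj_distance_ilp(inst$A_f, inst$B_f, inst$similarities)
sol
#> FFDCJ solution: optimal  distance = 2  |M| = 4  nodes = 63
sol$matching
#>   gene_a gene_b sigma
#> 1      1      7     1
#> 2      2      8     1
#> 3      3     10     1
#> 4      4      6     1
```

The optimum 2 means: after the best choice of one occurrence per family
(genes 5 and 9 of the relabeled B are excised), two DCJ operations
transform one genome into the other. It equals the brute-force exemplar
DCJ optimum `exemplar_dcj_bruteforce(g$A, g$B)$distance` — the two views
of the same instance agree, which the test suite checks systematically.

The same machinery from the shell (see `?ffdcj_run`):

```sh
Rscript inst/cli/ffdcj.R dcj --genomes genomes.txt
Rscript inst/cli/ffdcj.R distance --genomes genomes.txt --sim sim.tsv --solver ilp
Rscript inst/cli/ffdcj.R simulate --seed 7 --preset r2 --genes 30 --out-prefix sim
```

Input formats: UniMoG-style genomes (`>name` headers; chromosomes are
signed gene tokens ending in `|` linear / `)` circular) and three-column
TSV similarities (`gene_a  gene_b  sigma`).

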