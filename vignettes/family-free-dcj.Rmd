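---
title: "Family-free DCJ distance and similarity: models, algorithms, design notes"
author: "ffdcj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-free DCJ distance and similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffdcj)
```

## The problem

The double-cut-and-join (DCJ) operation cuts a genome at two positions and
rejoins the four open ends differently; it captures inversions,
translocations, fusions and fissions in one uniform move. The DCJ distance
between two genomes — the minimum number of such moves transforming one
into the other — is the workhorse dissimilarity of rearrangement-based
comparative genomics. Computing it classically requires genes to be grouped
into *families* so that content can be equated across genomes. That family
assignment is itself error-prone. The family-free approach skips it: each
gene keeps its own identity, and the only cross-genome information is a
*normalized similarity* $\sigma(a,b) \in (0,1]$ between gene $a$ of genome
$A$ and gene $b$ of genome $B$ (for instance a normalized alignment score;
this package treats $\sigma$ strictly as input). This package implements
the family-free DCJ distance and similarity, exact solvers for both, and
the generators needed to exercise them.

## Family-based background

A genome is a set of chromosomes, each an oriented sequence of signed
genes, linear or circular. Each gene $g$ has a *tail* $g^t$ and a *head*
$g^h$; an *adjacency* is a pair of consecutive extremities, or a single
extremity next to a telomere. For duplication-free genomes with equal gene
content, the *adjacency graph* $AG(A,B)$ has the adjacencies of $A$ and of
$B$ as its two vertex classes and one edge per gene extremity. All degrees
are 1 or 2, so the graph decomposes into cycles and paths, and

$$d_{DCJ}(A,B) = n - c - i/2,$$

with $n$ genes, $c$ cycles, and $i$ odd paths. Equivalently each component
$C$ with $|C|$ edges contributes $|C|/2-1$ (cycle), $(|C|-1)/2$ (odd path)
or $|C|/2$ (even path); `dcj_distance()` computes both routes and insists
they agree.

```{r}
gs <- parse_genomes(">A\n-1 3 4 2 |\n>B\n-2 1 4 3 |")
dcj_distance(gs$A, gs$B, census = TRUE)
```

## The family-free measures

The *gene similarity graph* $GS_\sigma(A,B)$ is the weighted bipartite
graph on the two (disjoint) gene sets with an edge of weight
$\sigma(a,b)$ wherever the similarity is positive. A matching $M$ of this
graph selects a tentative orthology: unsaturated genes are excised and each
matched pair is renamed to a shared label, giving *reduced genomes* $A^M$
and $B^M$ whose *weighted adjacency graph* carries $\sigma(e_i)$ on both
extremity edges of pair $i$ (so its total weight is $2\,w(M)$, asserted at
construction). Component $C$ contributes through $f(C) = 2|C| - w(C)$,
the simplest linear function that equals $|C|$ at unit weights and grows
as similarities shrink, yielding

$$d_\sigma(A^M,B^M) = \sum_C d_\sigma(C) = d_{DCJ}(A^M,B^M) + |M| - w(M).$$

`dsigma()` again evaluates both sides and errors if they disagree beyond
$10^{-9}$ — a deliberate guard against component-classification bugs.
Since the empty matching gives distance 0, minimization is restricted to
*maximal* matchings (no positive-similarity pair may simply be discarded):

$$d_{FFDCJ}(A,B) = \min_{M \in \mathbb{M}} d_\sigma(A^M, B^M).$$

The similarity counterpart normalizes component weight instead:
$s_\sigma = \sum_{cycles} w(C)/|C| + \sum_{odd} w(C)/(|C|+1) +
\sum_{even} w(C)/(|C|+2)$, maximized over maximal matchings. The
denominators are implemented literally as printed above; telomeric
"missing" edges never carry weight. The convex blend
$F_\alpha = \alpha\, s_\sigma + (1-\alpha)\, w(M)$ is provided
(`f_alpha()`), but no $\alpha$-tuning: choosing $\alpha$ is an open
modelling question, not something this package pretends to resolve.

Both optimization problems are computationally hard (the distance is even
hard to approximate), which shapes the solver design below. The hardness
constructions themselves ship as generators: `counterexample_instance()`
builds the family where the unique maximum-weight matching $M$ has
$d_\sigma = |M|$ while a lighter matching $M^*$ achieves
$\varepsilon|M^*|$, ratio $2/\varepsilon$ — the reason a maximum-weight
matching heuristic is not an approximation algorithm — and
`exemplar_to_ff_instance()` / `ff_matching_to_exemplar()` implement the
two directions of the reduction from the exemplar DCJ distance, which the
test suite uses as an independent oracle.

## Exact solvers

**Brute force.** `enumerate_maximal_matchings()` walks the edge list
depth-first (include if both endpoints free / exclude), filters maximal
leaves, and is capped (default $2^{20}$ states). It is the reference
implementation: slow, obviously correct, and the oracle for everything
else.

**ILP.** `build_distance_ilp()` constructs the standard model over the
graph $H$ on the extremity sets: matching edges $E_m$ (two per similarity
edge — head-head and tail-tail, weight $\sigma$), adjacency edges $E_a$
(forced), and self edges $E_s$ (excision). Constraints: degree one in
$E_m \cup E_s$ per vertex, head/tail consistency per similarity edge,
maximality (the two self edges flanking a similarity edge cannot both be
chosen), and label/counter variables $y_i, z_i$ that count cycles, with
counters only on $X_A$ vertices (indexed first, so only the smallest index
on a cycle can claim it). `ilp_write_lp()` exports this model in LP format
for any external MILP solver.

Two numerical choices deserve a note, both validated by the
oracle-equivalence suite (200 random instances, brute force vs. solver,
exact agreement):

* **Objective scaling.** Because every similarity edge appears as *two*
  matching edges in $H$, the implemented objective is
  $\sum_{e \in E_m} x_e - \tfrac12 \sum_{e \in E_m} w_e x_e - (\text{cycles})
  = 2|M| - w(M) - c$; a coefficient of 2 on the first sum would double
  count.
* **Path components.** A cycle counter alone cannot express the $i/2$
  odd-path term, and closing linear chromosomes with fixed-position cap
  genes does not fix this: with caps forced to join the two ends of their
  own chromosome and only the cap *pairing* free, the attainable cycle
  count can fall short of $c + i/2 + p$. (Concretely, for
  $A = \{(\circ\,1\,\circ),(\circ\,2\,\circ)\}$,
  $B = \{(\circ\,1\;2\,\circ)\}$ at unit weights the true distance is 1 —
  census two odd paths plus one even path — but both cap pairings yield
  only two capped cycles, not three.) The built-in solver therefore does
  not cap.

`solve_distance()` is an exact branch-and-bound solver specialized to the
model: it branches over the per-gene decision "match along edge $e$ /
excise", which fixes all binary variables (consistency and degree
constraints are implicit), prunes with the admissible bound
$\sum_{\text{decided}} (1-\sigma(e)) \le d_\sigma$ (each matched pair
contributes $2-\sigma$ to the linear part and at most 2 to $c + i/2$),
checks maximality at the leaves, and evaluates the exact objective by
walking the components of $H$ directly — the closed-form optimum of the
$y/z$ counters, extended with the path terms. Components containing no
matching edge (fully excised chromosome fragments) are skipped: they have
no counterpart in the reduced genomes, and crediting them — as the raw
label mechanics would for a fully excised circular chromosome — would bias
the optimization. The reported distance is always *recomputed* from the
returned matching via `dsigma()`, never read off the solver's internal
objective; at optimality the two are additionally asserted equal.

No ILP is provided for the similarity (brute force only), and no
approximation algorithm — the maximum-weight-matching heuristic is
provably unbounded, as the gadget shows.

## Synthetic instances

`simulate_pair()` emulates a rearrangement-evolution experiment at desk
scale: an ancestor with `n_genes` genes (default 25, one linear
chromosome) evolves into genome B through `n_rearrangements` random
inversions/translocations plus Poisson-distributed duplications and
losses; similarities are then degraded — true orthologs get
$\sigma = 1 - U(0, \texttt{weight\_noise})$ (default noise 0.1), paralog
copies get $\sigma \sim U(0.3, 0.9)$, and spurious edges appear between
unrelated pairs with probability 0.02. The preset $r \in \{1,2,5\}$ scales
event intensities the way 1×/2×/5× duplication/loss/rearrangement rates
scale a pairwise comparison: with per-gene rates of 0.0025
(rearrangement) and 0.001 (duplication, loss) over a pairwise divergence
of 200 time units, the expected per-gene event counts are $0.5r$ and
$0.2r$; those products are the defaults. The generator returns the
ground-truth orthology matching, enabling parameter-recovery experiments
(under mild noise, the brute-force optimum recovers the truth in at least
90% of seeded replicates in the test suite).

What the simulator does *not* emulate: sequence evolution (similarities
are drawn, not computed from sequences), gene-length variation, more than
two genomes, and genome sizes beyond a few dozen genes. Passing tests on
these instances validate the combinatorics and the optimizers, not the
biological realism of $\sigma$.

## Numerical and design choices

* Weights and derived quantities are compared at $10^{-9}$ absolute
  tolerance; all printed quantities in the worked examples are short
  decimals, so this is far below any meaningful difference. The
  family-based distance is additionally asserted to be a non-negative
  integer.
* Reduced-genome labels are assigned by first occurrence along genome A —
  the bijection is mathematically arbitrary, a fixed rule just makes
  output reproducible.
* Genes with no similarity edge are removed before building $H$; they can
  only be excised and would otherwise create matching-free components.
* The five/six-gene worked example pins down only matching-level
  aggregates (sizes, weights, component censuses), not per-edge weights;
  `search_matching_by_census()` reconstructs a matching realizing a given
  census deterministically, which is how the documented values 3.3 and
  3.1 are reproduced without inventing unprinted data.
* Problem sizes in the test suite (up to 6 genes per genome, 12 similarity
  edges, 200 oracle instances; 50 exemplar instances; 30 circular
  similarity gadgets) are chosen so the brute-force oracles stay exact
  and instant while still exercising every component type — cycles, odd
  and even paths, excisions, circular and multi-chromosomal genomes.
* Ties between optimal matchings are broken by search order; tests compare
  distances, never matchings, except where a matching is unique.

## Known limitations

* The exact solvers are for small instances (tens of genes); the LP export
  exists precisely so that large instances can be handed to an industrial
  MILP solver.
* Indels are not modelled (excision by the matching is not a biological
  deletion model), and no rearrangement scenario is reconstructed — the
  package computes distances and similarities, not sorting sequences.
* The similarity optimizer is brute-force only.
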