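---
title: "Family-free gene order comparison: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-free gene order comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffadj)
```

## Why family-free?

Gene order analyses usually start from gene families: genes are clustered
by sequence similarity, chromosomes become words over the family alphabet,
and combinatorial machinery (breakpoints, common intervals, rearrangement
distances) takes over. The clustering step, however, imports arbitrary
thresholds, cannot separate in- from out-paralogs without a gene tree, and
hard binary family membership discards exactly the graded signal that
sequence comparison produces. `ffadj` works directly on a normalized
pairwise similarity measure σ : genes × genes → [0, 1] instead. Matching
genes between two genomes and counting conserved adjacencies then happens
in a single optimization that can trade sequence similarity against
positional conservation.

## The model in detail

A genome is one linear chromosome: a sequence of signed genes at positions
`1..n−1` flanked by two unsigned telomeres at positions `0` and `n` (a
genome with `n − 1` genes has *size* `n`). Circular chromosomes are cut at
a user-chosen origin (`linearize_circular()`); the cut can cost at most the
one adjacency spanning it against a fixed partner, although the telomeric
adjacencies introduced by the cut mean that the *total* count across
origins can vary by up to three (one circular adjacency plus the two
telomeric ones that appear only when the cuts of both genomes align).

`build_graph()` connects the two position sets: gene pairs with σ > 0 get
an edge of weight σ, the four telomere–telomere edges are always present
with weight 1, and gene–telomere edges never exist. Genes without any
positive cross-genome similarity cannot be matched and are removed up
front, positions re-indexed (the removed identifiers are kept on the graph
object). Connected components of the remaining graph — computed with
`igraph` — generalize gene families: they are the sets of genes tied
together by any chain of similarity.

A matching `M` (class `ffadj_matching`) holds disjoint gene edges plus
exactly two telomere edges, parallel (`e_{0,0}`, `e_{n1,n2}`) or crossed
(`e_{0,n2}`, `e_{n1,0}`). Two matched pairs `(i, k)` and `(j, l)` with
`i < j` form a conserved adjacency iff

1. no saturated gene lies strictly between `i` and `j`, nor between
   `min(k, l)` and `max(k, l)` (*consecutive pairs* — unsaturated or
   removed genes in between do not interfere);
2. for `k < l` the strand signs agree pairwise, for `k > l` they differ
   pairwise; telomeres (sign 0) satisfy either condition, which is what
   lets crossed telomere edges close adjacencies on fully reversed
   genomes.

The adjacency contributes `w(e_ik) · w(e_jl)`. The two scores are

* `adj(M)` — sum of conserved-adjacency products;
* `edg(M)` — sum of squared edge weights. Squaring puts edges on the same
  scale as the adjacency products, so `α` trades like against like.

and the objective is `F_α(M) = α·adj(M) + (1−α)·edg(M)` for `α ∈ ]0, 1]`,
maximized subject to at least one edge per component (the *intermediate*
model, between the exemplar and maximum models). At `α = 1` only
adjacencies count; as `α → 0` the optimum approaches a maximum weighted
matching that still prefers adjacencies among ties.

### Telomere conventions

Telomere edges are full members of the matching: they contribute 1 each to
`edg` and participate in adjacencies. With this convention the derived
distance

`Δ(M) = (#edg(M) − #adj(M) − 1) / #edg(M)`

(counts, telomeres included) is exactly 0 for identical gene orders: `n`
matched genes give `#edg = n + 2` and `#adj = n + 1`. The `− 1` mirrors
the classical relation between breakpoints and adjacencies on linear
chromosomes. A weighted variant (`delta_distance(m, weighted = TRUE)`)
replaces the counts by `edg`/`adj`; both coincide under unit weights, and
the count form is the default because the distance is meant to estimate
the *number* of breakpoints, not their weight. For degenerate inputs where
every gene was pruned, `Δ` is defined as 0 with a warning rather than an
error, so all-vs-all distance matrices never abort on an empty overlap.

## The exact solver

`build_ilp()` translates the problem into a 0-1 linear program in the
classical four-variable family:

* `a(i,k)` — edge `e_ik` in the matching; defined only where σ > 0, plus
  the four telomere edges;
* `b_x(i)` — position `i` of genome `x` saturated;
* `c_x(i,j)` — positions `i < j` form a consecutive pair; only the upper
  bounds `c_x(i,j) + b_x(p) ≤ 1` (for `i < p < j`) are imposed. A `c` that
  is "too true" (e.g. when `i` itself is unsaturated) never helps the
  objective, so no lower bounds are needed;
* `d(i,j,k,l)` — the quadruple is a conserved adjacency; bounded above by
  its four factors (`a(i,k)`, `a(j,l)`, `c1(i,j)`, `c2(min,max)`). Since
  `d` carries a strictly positive objective coefficient `α·s(i,j,k,l)`
  under maximization, upper bounds alone make it exact.

`d` variables are only instantiated for quadruples whose fixed gene signs
can satisfy the orientation conditions and with `k ≠ l` — a syntactic
screen that shrinks the `O((n1·n2)²)` variable set considerably. The
single space-reduction rule fixes every two-gene component: its edge must
be in any intermediate matching, so `a = b = 1` and all consecutiveness
variables spanning the fixed positions (with their dependent `d`s) drop
to 0. Telomere positions are fixed saturated, and the four telomere edges
form exactly one parallel or crossed pair.

No mixed-integer solver library is attached: the program is solved by an
exact depth-first branch-and-bound written for this variable structure. It
branches over the `a` variables one genome-1 position at a time; for a
full `a` assignment all other variables are determined (`b` by summation,
`c` maximally, `d` as the product of its factors), so leaves are evaluated
directly through the model's `d` table. Two admissible prunings keep the
tree small: a per-position optimistic bound (each additional edge `e` can
contribute at most `2αw(e) + (1−α)w(e)²`, since it sits in at most two
adjacencies whose partner weight is at most 1) and a component dead-end
check (a component whose last selectable position passes uncovered can
never become covered). The search is deterministic; ties keep the first
optimum in enumeration order. `write_lp()` exports the full model in the
standard LP text dialect for inspection or external solvers. The default
time limit is 300 s per instance; on expiry the best incumbent is returned
flagged non-optimal (and `pairwise_distance_matrix()` either substitutes
the heuristic value or records a missing entry, per its `fallback`
argument).

The solver is validated against `brute_force_optimum()`, an independent
oracle that enumerates every vertex-disjoint, component-covering edge
subset under both telomere orientations and scores it through the
matching-model functions. The two code paths share no scoring code; their
agreement on hundreds of seeded instances across the studied α grid
(0.001, 0.3, 0.5, 0.8, 1) is the package's central correctness check.

## The heuristic

`run_heuristic()` generalizes iterative longest-common-substring matching
to weighted, family-free input. Each iteration:

1. enumerates all maximal runs of unmatched gene pairs that are
   σ-connected and sign-consistent, forward or under complete reversal
   (reverse order, opposite signs). "Consecutive" here skips matched and
   deleted positions; length-1 runs are admitted, which is what guarantees
   the stopping rule below terminates with full saturation;
2. matches the run with the best local score
   `α · Σ consecutive products + (1−α) · Σ σ²` (ties: smallest start
   positions, forward before reversed — determinism is needed for testing;
   the classical formulation chooses arbitrarily);
3. deletes *hopeless* genes — unmatched genes with no unmatched σ-partner
   left — to a fixed point, then tries to extend every previously matched
   run across the freed flanks, pairing nearest unmatched flanking genes
   of the run's own orientation.

Iteration stops only when no σ > 0 edge remains between unmatched genes.
Full saturation implies every component is covered, so the result is
always a valid intermediate matching; it also keeps `edg` high at `α = 1`,
where the exact solver is free to drop isolated pairs that close no
adjacency. Matched genes are never unmatched: the procedure is greedy and
bounded by the total gene count.

Three readings of the informal procedure were fixed as design choices:
candidate runs skip matched and deleted positions (consistent with the
consecutive-pair definition); the local score counts only within-run
terms, not junctions with earlier segments (those are captured by the
final objective anyway); and extensions keep the segment's orientation.
Telomeres are pre-matched parallel and flipped to crossed at the end if
that strictly improves `F_α` — the natural completion for fully reversed
genomes.

## Phylogenies

`pairwise_distance_matrix()` assembles the Δ matrix for a genome set with
either matcher. `neighbor_joining()` is a deterministic in-package
Saitou–Nei implementation (lowest-index tie-break, negative branch length
clamped to 0 with a warning) returning an `ape` tree; `rf_distance()`
counts the symmetric difference of non-trivial bipartitions of the
unrooted topologies. Both are cross-checked in the tests against the
independent implementations in `ape` and `phangorn`. Newick parsing and
serialization are delegated to `ape`; PHYLIP square matrices and NEXUS
distance blocks are written for downstream tools (split networks etc.).

## The simulator

`simulate_pair()` generates the study conditions all randomized tests run
under. An ancestor of `n_genes` signed genes is copied; the second genome
then undergoes `n_inversions` interval reversals (signs negated),
`n_duplications` copy insertions and `n_losses` deletions, in that order,
at uniformly sampled loci from one seeded generator. σ connects genes of
shared ancestral origin with weight `sigma_true · sigma_decay^d` (d = the
accumulated duplication generation) under a mild multiplicative jitter in
[0.95, 1], emulating the in/out-paralog ambiguity that family-free
comparison must resolve; a Poisson(`noise_edges`) number of spurious
edges with weights below `noise_weight_max` is added between
non-homologs. The planted matching pairs each ancestor gene with its
least-duplicated surviving copy; when noise creates a component without
any planted edge, the heaviest edge of that component is added so the
planted matching is always a valid intermediate matching (and hence a
feasible lower bound for the optimizers). `simulate_tree_dataset()` runs
the same branch process independently along every edge of a guide
topology and emits leaf genomes plus all pairwise σ.

Defaults (`n_genes = 10`, 2 inversions, 1 duplication, 1 loss,
`sigma_true = 0.9`, `sigma_decay = 0.7`, `noise_edges = 2`,
`noise_weight_max = 0.3`) describe a moderately rearranged pair with
sparse, high-contrast similarity — the regime a reciprocal-BLAST σ over
related bacterial genomes produces. What the simulator does *not*
emulate: sequence evolution itself (σ is drawn, not computed from
sequences), transpositions, gene fusion/fission, horizontal transfer, and
multichromosomal genomes. Passing tests therefore certify the
combinatorial machinery under the stated event model, not robustness to
every real σ.

### Problem sizes in the validation suite

The exactness checks run 200 instances of 5 ancestral genes (at most 6
genes per genome after one duplication) across five α values — small
enough for the enumeration oracle yet large enough to exercise pruning,
components, duplicates and noise. Phylogeny recovery uses 20 seeded
4-leaf datasets of 10 genes with one inversion/duplication/loss per
branch (exact matcher, α = 0.5), and an 8-leaf paired comparison of
heuristic against exact trees. These sizes were chosen so the whole suite
exercises every code path at interactive turnaround.

## Numerical and interface conventions

* All floating-point comparisons use absolute tolerance 1e−9 (1e−6
  between solver objective and re-scored matching, matching the looser
  guarantee a MILP gap would give).
* α is validated against `]0, 1]` everywhere; `α = 0` is rejected rather
  than silently treated as maximum weighted matching.
* Similarities must lie in (0, 1]; zero entries are dropped on input,
  values above 1 are an input error. The similarity lookup is symmetric
  in its two identifiers.
* The RRBS construction
  `σ(g1,g2) = (bs(g1→g2) + bs(g2→g1)) / (bs(g1→g1) + bs(g2→g2))` with
  reciprocity required and clamping at 1 is one of several forms in the
  literature; it is a documented assumption, kept behind its own function
  so an alternative normalization can be swapped in.
* One linear chromosome per genome; multi-genome files are supported but
  each genome is a single chromosome, and `read_genome()` refuses
  ambiguous multi-genome files unless a name is given.
* Exit codes of the command-line interface: 0 success, 1 usage error,
  2 data error, 3 solver failure.

## Known limitations

The exact solver's memory and time grow combinatorially; it is intended
for small genomes or the dense-information regime after pruning, with the
heuristic (linear-ish in practice) as the production path for full
genomes. Only the single two-gene reduction rule is applied; further
model reductions and a hybrid heuristic-then-exact scheme are natural
extensions. The distance Δ compares a single optimal matching; degenerate
optima with different adjacency counts are resolved by a deterministic
tie-break, not enumerated.
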