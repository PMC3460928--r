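---
title: "Methods: modularity, nestedness and robustness of tree-hollow food webs"
author: "hollownet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modularity, nestedness and robustness of tree-hollow food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hollownet)
```

## The data model

All analyses consume a `bipartite_network`: a matrix of non-negative
integer counts whose rows are tree hollows (lower trophic level) and whose
columns are insect species (higher trophic level), plus a guild code per
species (A saprophagous, B xylomycetophagous, C xylophagous, D commensal,
E predator). The orientation is fixed package-wide; every downstream
function assumes it. A *link* is any cell with count ≥ 1. Weighted
metrics (linkage density, H2′, species strength, variance ratio) use the
counts; NODF, modularity and the extinction simulations use
presence/absence, matching the binary tools classically used for those
analyses. An *analysis-ready* network has no empty rows or columns;
guild filtering re-compacts rows, which is why sub-networks report fewer
participating hollows than the complete web.

Ids are opaque strings ordered lexicographically on input, so assembly
from edge lists is deterministic and write/read round-trips are exact.

## Nestedness: NODF and the CE null

`nodf()` implements overlap-and-decreasing-fill nestedness: for every
pair of rows whose marginal totals differ, the pair contributes 100 ×
(shared presences) / (smaller marginal total); equal totals contribute 0;
the same over column pairs; NODF is the mean across all pairs. The rule
is stated on marginal totals, not on row positions, so the score is
invariant under permutation of rows and columns — sorting the matrix
first (as reference implementations do) yields the same value, which the
test suite checks against `vegan::nestednodf` on sorted matrices and
against a literal pair-enumeration oracle on all valid 3×3 binary
matrices.

`nestedness_test()` scores significance against the CE null model, in
which the probability of cell (i, j) is the mean of row i's fill and
column j's fill, so generalisation levels of both partners drive the
null. Two numerical choices matter:

* Null draws occasionally produce empty rows or columns; these are
  *compacted* (dropped), not redrawn, keeping the estimator defined
  without biasing occupied cells. Draws left with fewer than two rows or
  columns score 0 (they contain no scorable pairs).
* The one-sided p-value uses add-one smoothing,
  p = (1 + #{null ≥ observed}) / (1 + replicates), so a finite
  Monte-Carlo null never reports p = 0. The default of 1000 replicates
  follows standard practice for this test.

## Modularity by simulated annealing

For a partition of the *unipartite* node set (hollows and species
together) modularity is

M = Σ_s [ l_s / L − (d_s / 2L)² ],

with L the total links, l_s the links within module s and d_s its degree
sum. M is exactly 0 for the single-module partition and ~0 for random
assignments; the random-assignment expectation carries a finite-size bias
of order Σ deg² / (4L²), which is why the "random ≈ 0" property is tested
on a moderately sized fixture. Partitioning the two node sets jointly
(rather than a bipartite-specific modularity) is deliberate: module
composition across both levels — which hollows travel with which species
— is the object of interest.

`sa_optimize()` anneals cost C = −M from a singleton partition. At each
temperature it proposes `updates_per_T` single-node reassignments
(including moves to a fresh empty module) plus `round(f × n_nodes)`
collective moves (random merges and random-bisection splits), accepting
with the Metropolis probability min(1, exp(−ΔC/T)); the temperature is
then multiplied by the cooling factor. Defaults: 1000 updates per
temperature, iteration factor f = 0.1, cooling factor c = 0.995. The
published description of this schedule leaves the interaction of the
update count and f open; the reading adopted here — a fixed single-node
budget, with f scaling only the collective moves — is documented as a
package choice, not asserted as the original tool's exact schedule.

Two schedule parameters are not stated anywhere and are auto-derived:
the initial temperature starts at 1/(2L) and is scaled up until roughly
half of trial proposals would be accepted (so early exploration is
genuinely hot), and the final temperature defaults to 10⁻⁴ of the
initial one, by which point acceptance of uphill moves is negligible.
The best partition ever visited is returned, so the reported M can never
fall below the best local optimum encountered. The inner loop is
compiled (Rcpp) and draws from R's RNG, so runs are reproducible under a
seed. On networks of ≤ 8 nodes the suite verifies the annealer attains
the global optimum found by Bell-number enumeration, and on planted
4-block 60×40 networks (p_in = 0.5, p_out = 0.02) it recovers the
planted partition with NMI ≥ 0.9.

**Consensus.** `consensus_runs()` repeats the anneal (default 25 runs,
consecutive seeds) and tabulates the module-count distribution as
percentages of runs. The *selected* partition is the "minimum partition
with largest optimisation of modularity": among runs within 1% of the
best M, the one with fewest modules, ties broken by higher M and then
lower run index — fully deterministic. Because "appearing together" is
not well defined for node *sets*, cohesion of a selected module is
reported two ways: the pairwise version (mean fraction of the module's
node pairs co-assigned per run; singletons score 1) and an all-or-nothing
version (fraction of runs in which the whole set is co-assigned).

**Significance.** `modularity_significance()` compares the observed M
against networks randomised by checkerboard swaps, which preserve both
degree sequences — the conservative choice when the original
randomisation is unspecified. Each null receives the same annealing
budget. The default of 199 nulls makes the smallest achievable smoothed
p-value 1/200 = 0.005, the natural resolution for p-values of that
magnitude; a run that fails to reach 10 × L successful swaps is flagged
in the result rather than silently accepted.

**Component counts.** The panel's M column counts graph components
(isolated sub-webs), not annealed modules: isolated modules in the
ecological sense are detached pairs or small sets of interacting nodes,
which is exactly what components measure.

## Node cartography

Within-module degree z standardises a node's within-module link count
against its module (population standard deviation, as the formula's plain
reading implies); modules whose members all tie get z = 0, avoiding a
0/0. The participation coefficient is P_i = 1 − Σ_s (k_is/k_i)². Roles:
non-hubs (z < 2.5) are R1 (P ≤ 0.05), R2 (P ≤ 0.62), R3 (P ≤ 0.80), else
R4; hubs (z ≥ 2.5) are R5 (P ≤ 0.30), R6 (P ≤ 0.75), else R7. Only the
z ≥ 2.5 hub cut is stated in the source methodology; the P cut-points are
adopted from the standard functional-cartography scheme and exposed as a
configurable table (`role_thresholds`). All upper bounds are inclusive,
so the classification is total, including boundary cases.

## The metric panel

* **Links per species** divides the link total by the count of *all*
  nodes (species + hollows). This reading is forced by internal
  arithmetic of the classical panel: with 21 species, 80 hollows and
  2.614 links per species, 2.614 × 101 = 264 links and 264/1680 = 0.157
  reproduces the printed connectance — a consistency the acceptance
  suite recomputes.
* **Connectance** is links divided by matrix cells.
* **Species strength** sums, over hollows, the fraction of each hollow's
  individuals contributed by the species; strengths sum exactly to the
  hollow count. The transposed variant is available via a flag.
* **Linkage density** is the quantitative (entropy-based) version: each
  node contributes its effective partner number 2^H weighted by its
  share of the grand total. The one-line gloss "mean number of
  interactions per species" cannot be what produced the classical
  panel's values (they exceed links per species), so the quantitative
  variant is implemented and the discrepancy documented here.
* **H2′** standardises the two-dimensional Shannon entropy of the
  interaction matrix between the extremes attainable under the observed
  marginal totals: H2min by greedy diagonal packing, H2max by
  proportional allocation with unit-by-unit integer repair. Integer
  marginals make the extrema slightly non-unique; a 0.05 tolerance
  absorbs this, and tiny-matrix tests compare both heuristics against
  exhaustive enumeration of all tables with the same margins. The
  degenerate case H2max = H2min returns 0 with a `degenerate` attribute.
* **Variance ratio** compares the variance of per-hollow totals with the
  summed per-species variances (population form); 1 under independence,
  greater under aggregation, smaller under compensation. Abundance-based
  by default ("species numbers to individual numbers" is ambiguous); a
  presence/absence flag is provided.

## Extinction robustness

Hollows are removed one at a time, uniformly at random or most-connected
first (degree ties broken by seed); a species goes secondarily extinct
when its last linked hollow disappears. x counts the fraction of hollows
removed *including the current one*, survival is recorded after each
removal, and the curve runs from (0, 1) to (1, 0). Robustness R is the
trapezoidal area under the curve; the slope is the exponent a of a
least-squares fit of y = 1 − x^a, fitted by one-dimensional minimisation
over log a (no convergence failures on monotone curves). For exact
curves of that family R = a/(a+1), an identity the suite checks to
±0.05 across a ∈ {0.5, 1, 2, 5, 8} — and which also ties the two
robustness columns of the classical panel together. Random-order slope
and area are averaged over replicates (default 100); the degree order is
deterministic up to ties, so it is replicated only when ties exist.
Removal acts on hollows only: removing insects does not destroy
microhabitats, so the reverse simulation is not meaningful here.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical* structure the analyses
consume, not any ecological dynamics (no phenology, no trapping process,
no real community):

* `generate_modular()` plants an even block structure with within/between
  link probabilities p_in/p_out, giving ground truth for recovery and
  component tests. Positive counts are 1 + geometric (mean defaulting
  to 3), so weights are heavy-tailed like real emergence counts dominated
  by a few abundant generalists. Isolated nodes are repaired with one
  within-block link rather than dropped, keeping the planted partition
  intact. Note the planted blocks are Bernoulli graphs: with p_out = 0
  the component count equals the block count only when each block is
  internally connected, so disconnection-sensitive tests use dense
  blocks.
* `generate_nested()` builds the staircase (upper-left triangular)
  matrix, the canonical perfectly nested pattern with strictly
  decreasing margins on square matrices; NODF = 100.
* `generate_independent()` draws each species' abundances independently
  (Poisson, species means lognormal around the requested mean, sdlog
  0.3), the null fixture under which the variance ratio is centred on 1.
* `generate_paper_scale()` emulates a full survey: 87 hollows × 157
  species, connectance ≈ 0.09, five planted blocks, lognormal expected
  species degrees (sdlog 1.4, rescaled to pin the link total) so that
  roughly half the species hold 1–3 links, hollow attractiveness
  lognormal (sdlog 0.6) standing in for hollow size, and guild counts
  21 C / 44 A / 38 B / 26 E / 28 D (a published guild table scaled by
  largest remainder from 158 to the 157 species used here). Passing
  tests on this fixture show the pipeline reproduces *structural*
  features at survey scale; they do not validate any claim about a real
  community, whose raw matrix is not public.

No degree-distribution family is prescribed by the source methodology;
block-Bernoulli links with geometric counts are a modelling choice and
are flagged as such.

## Determinism and problem sizes

Every stochastic function takes a seed and restores the caller's RNG
state; the pipeline derives one sub-seed per stage by stable hashing of
the stage name, so adding a stage never shifts another stage's stream,
and repeated seeded runs are byte-identical. Defaults follow the full
study protocol (1000 nestedness replicates, 25 consensus runs, 100
robustness replicates, 199 modularity nulls). The test suite exercises
the same code paths at reduced Monte-Carlo sizes chosen to keep the suite
fast while leaving the checked properties unchanged — e.g. the
survey-scale end-to-end determinism test uses 100 nestedness replicates,
5 consensus runs, 20 robustness replicates and 19 nulls, and the
planted-recovery experiment uses ten 60×40 fixtures.

## Known limitations

* H2min/H2max are heuristics; on large matrices they may differ from the
  true integer extrema by more than the tiny-matrix tolerance, though
  the standardisation is insensitive to this in practice.
* The annealer's split move is a random bisection refined only by
  subsequent single-node moves; pathological module shapes could in
  principle require more aggressive splits than the default budget.
* The CE compaction convention and the exact annealing schedule are
  package choices where the original tooling is under-specified; both
  are isolated behind the documented interfaces.
* Forest-type labels are carried but unused: micro-environmental
  covariates are out of scope.
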