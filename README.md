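# hollownet

Quantitative analysis of bipartite ecological networks between tree-hollow
microhabitats and the saproxylic insect communities that emerge from them.

Tree hollows in mature forests house a large share of forest insect
biodiversity. Each hollow is a microhabitat; each insect species emerging
from it is a consumer of the resources the hollow provides (dead and decaying
wood, wood-inhabiting fungi, or other saproxylic insects). Sampling many
hollows yields a weighted bipartite network: rows are hollows (lower trophic
level), columns are insect species (higher trophic level), and weights are
counts of emerged individuals. Species carry a feeding-guild annotation —
saprophagous (A), xylomycetophagous (B), xylophagous (C), commensal (D),
predator (E) — which splits the community into wood-dependent (A–C) and
insect-dependent (D–E) sub-networks.

`hollownet` implements the full analysis workflow for such data:

* **Sub-network decomposition** — complete network, wood-/insect-dependent
  levels, and single-guild sub-networks, dropping hollows emptied by the
  filter.
* **Nestedness** — the NODF estimator (percent overlap under decreasing
  marginal fill, averaged over row and column pairs, 0–100) with a
  Monte-Carlo significance test against the CE null model, in which cell
  (i, j) is occupied with probability `(fill_row_i + fill_col_j) / 2`.
* **Modularity** — Newman–Girvan modularity on the unipartite view,

  `M = Σ_s [ l_s/L − (d_s/2L)² ]`

  (L links in total; `l_s` within-module links and `d_s` degree sum of
  module s), maximised by simulated annealing with single-node and
  split/merge moves under the Metropolis rule `p = min(1, exp(−ΔC/T))`,
  cost `C = −M`, geometric cooling. Multi-run consensus reports the
  module-count distribution, the minimum partition with largest
  modularity, and per-module cohesion; significance is assessed against
  degree-preserving (checkerboard-swap) null networks.
* **Node cartography** — within-module degree z-score (hubs at z ≥ 2.5),
  participation coefficient `P_i = 1 − Σ_s (k_is/k_i)²`, and the universal
  roles R1–R7 (ultra-peripheral → kinless hub).
* **Metric panel** — links per species, connectance, quantitative linkage
  density (entropy-based effective partners), species strength (sum of
  dependencies), H2′ specialisation (standardised two-dimensional entropy,
  0–1), and the variance ratio (aggregation vs. compensation).
* **Robustness** — random and most-connected-first removal of hollows with
  secondary extinction of species, survival curves, area-under-curve
  robustness R, and the fitted exponent of `y = 1 − x^a` (for which
  R = a/(a+1)).
* **Synthetic data** — seeded generators for planted-modular,
  perfectly-nested, independent-abundance and survey-scale networks, so
  every stage is testable without field data.

## Worked example

```r
library(hollownet)

net <- generate_paper_scale(seed = 1)   # synthetic survey-scale fixture
net
#> Bipartite hollow-species network
#>   87 tree hollows x 157 insect species, 1259 links, 3831 individuals
#>   guilds: A=44 B=38 C=21 D=28 E=26

xyl <- extract_subnetwork(net, "C")     # xylophagous sub-network
rep <- full_report(xyl, nestedness_replicates = 1000,
                   robustness_replicates = 100, seed = 1)
round(as.data.frame(rep), 3)
#>   SP TH   NODF NODF_p M   L_S     C    LD    H2 V_ratio    PE   RPE    SE   RSE
#> 1 21 62 29.901  0.001 3 1.771 0.113 7.648 0.565   1.026 3.113 0.737 1.397 0.588

cons <- consensus_runs(xyl, n_runs = 25, sa_params(seed = 1))
cons
#> Consensus over 25 annealing runs
#>   module-count distribution (% of runs):
#>  5  6  7  8
#> 24 48 20  8
#>   selected: run 25, 6 modules, M = 0.4131
#>   module cohesion (pairwise co-assignment):
#> module1 module2 module3 module4 module5 module6
#>   0.714   0.885   0.878   0.795   0.793   0.393
```

Reading the report row: the sub-network keeps 21 xylophagous species across
the 62 hollows they occupy; 147 links give connectance C = 0.113 and 1.771
links per node; H2′ = 0.565 indicates substantial specialisation; NODF is
29.9. PE/RPE are the slope and area-under-curve robustness for random hollow
loss (100 replicates), SE/RSE for targeted removal of the most-connected
hollows. The consensus shows the annealer most often resolves 6 modules
(48% of 25 runs) and how stably each selected module's node pairs travel
together across runs.

The full pipeline over all eight networks (complete, direct, indirect, five
guilds) is one call, writing panel/consensus/cartography/robustness tables
plus a manifest:

```r
run_all(run_config(out_dir = "out", seed = 1), net = net)
```

A command-line wrapper with `run`, `validate` and `fixtures` subcommands is
installed at `inst/scripts/run_pipeline.R`.

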