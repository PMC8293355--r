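# bridgenet

Multilayer partial-correlation networks of cognition and brain structure:
estimation, bridge centrality, community detection, and bootstrap
stability, with a calibrated synthetic-data generator.

## What this is for

Researchers studying how cognitive abilities and brain structural
covariance relate often place both kinds of variables in a single
undirected network — a Gaussian graphical model (GGM) whose edges are
**partial correlations**: for precision matrix $K = \Sigma^{-1}$,

$$\rho_{ij} = -\frac{\kappa_{ij}}{\sqrt{\kappa_{ii}\,\kappa_{jj}}},$$

the association between nodes $i$ and $j$ after conditioning on every
other node. bridgenet implements the full analysis pipeline for such
multilayer (cognition + grey matter + white matter) networks:

- **Estimation** — Pearson correlations with pairwise deletion for
  missing data, positive-semidefinite repair, and the graphical lasso
  along a 100-step penalty path with EBIC model selection
  ($\gamma = 0.5$): $\mathrm{EBIC}_\gamma = -2\ell(\hat K) + E\log n +
  4E\gamma\log p$.
- **Centrality** — node strength $s_i = \sum_j |w_{ij}|$ and bridge
  strength $b_i = \sum_{j:\,c_j \ne c_i} |w_{ij}|$ (edges crossing
  community boundaries), z-scored with a one-SD rule for calling nodes
  central.
- **Communities** — Walktrap (random-walk distances, Ward merging,
  deterministic tie-breaks) cut at maximum weighted modularity $Q$.
- **Stability** — case-drop bootstrap correlation-stability (CS)
  coefficients for centrality orderings and percentile bootstrap
  intervals for edge weights.
- **Synthetic data** — planted population networks
  (`build_preset()`) calibrated to published single-layer edge summaries,
  with nested layer sample sizes (805 / 246 / 165) and per-task
  missingness, so every stage is testable without restricted cohort data.

See the vignette (`vignettes/multilayer-networks.Rmd`) for the models,
defaults, and design decisions in detail.

## Worked example

Simulate the cognitive layer at the study's sample size and run the
single-layer pipeline, then the tri-layer analysis:

```r
library(bridgenet)

cfg <- run_config(preset = "calm_cognitive", n = 805, seed = 1,
                  bootstrap = list(B = 200))
report <- run_single_layer(cfg, "cognition")
print(report)
#> bridgenet single_layer run: layers = cognition (seed 1)
#> Edge weights (age excluded): mean = 0.08, median = 0.05, range = 0.00-0.59 (39 of 45 nonzero)
#> Central nodes: Read, Spell
#> Centrality stability: CS = 0.45 (moderate)

tri <- run_config(preset = "calm_trilayer", n = 805, seed = 1)
mrep <- run_multilayer(tri, c("cognition", "grey", "white"))
print(mrep)
#> bridgenet multilayer run: layers = cognition+grey+white (seed 1)
#> Edge weights (age excluded): mean = 0.03, median = 0.00, range = -0.06-0.56 (182 of 435 nonzero)
#> Walktrap partition: 4 communities, Q = 0.392 (moderate modularity)
#>   [1] NO, Read, Spell, Pea, MR, DR, BDR, Dot, MrX, FI
#>   [2] CAC, CMF, MOF, RAC, RMF, SFG
#>   [3] FP, ATR, CST, CING, CINGh, FMaj, FMin, IFOF, ILF, SLF, UNC, Age
#>   [4] STG, SMG, TTG
#> Central nodes: NO, MR, RMF, SFG, STG, SMG
```

Reading the single-layer output: the estimated network's unique non-age
edge weights average 0.08 with one strong edge (reading–spelling, planted
at 0.63 in the population and estimated at 0.59 here); reading and
spelling exceed one SD above mean strength; and 45% of the sample can be
dropped while the strength ordering stays correlated ≥ 0.7 with the full
sample at 95% probability. In the tri-layer run, Walktrap recovers the
layer structure almost exactly (communities split along cognition / frontal
grey matter / temporal grey matter / white matter), and the central
(bridge) nodes are those carrying the planted cross-layer edges.

A thin command-line wrapper is included at `inst/cli/bridgenet.R`:

```sh
Rscript inst/cli/bridgenet.R simulate --preset calm_trilayer --n 805 --seed 1 -o data/
Rscript inst/cli/bridgenet.R run --config cfg.json
```

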