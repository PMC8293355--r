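---
title: "Multilayer partial-correlation networks: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer partial-correlation networks: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Individual differences in cognitive ability covary with individual
differences in brain structure, but the two levels rarely map onto each
other one-to-one. One way to study them jointly is to place cognitive task
scores and regional brain measures — here grey-matter cortical volume (CV)
and white-matter fractional anisotropy (FA) — into a single *multilayer
network*: an undirected Gaussian graphical model (GGM) whose nodes span
both levels and whose edges are partial correlations, the association
between two variables after conditioning on every other variable in the
set. bridgenet implements this pipeline end to end: regularized network
estimation from incomplete data, strength and bridge-strength centrality,
Walktrap community detection with weighted modularity, and bootstrap
stability diagnostics. Because the motivating cohort data (a developmental
sample of struggling learners with nested neuroimaging subsamples) cannot
be shared, the package ships a calibrated synthetic-data generator so the
full pipeline is testable against planted ground truth.

## The model

For variables $X \sim N(0, \Sigma)$ with precision matrix
$K = \Sigma^{-1}$, the partial correlation between nodes $i$ and $j$ given
all others is

$$\rho_{ij} = -\frac{\kappa_{ij}}{\sqrt{\kappa_{ii}\,\kappa_{jj}}},$$

so zeros of $K$ are missing edges. The population presets store a planted
partial-correlation matrix $P$; fixing unit partial variances gives
$K = I - P$, and `pcor_to_covariance()` returns $K^{-1}$ rescaled to unit
marginal variances (rescaling leaves all partial correlations untouched,
which is why the round trip through `covariance_to_pcor()` is exact to
numerical precision — a property the test suite asserts at `1e-10`).

## Estimation

`pairwise_pearson()` computes Pearson correlations on pairwise-complete
observations, records the per-pair counts, and defines the effective
sample size `n_effective` as the number of subjects with at least one
observed value (a `min_pairwise` alternative is available; the choice is a
genuine judgment call under pairwise deletion, and both are defensible).
Pairwise deletion can produce an indefinite matrix; `nearest_psd()` clips
eigenvalues at `1e-8` and rescales to unit diagonal, and the repair
magnitude is carried into the network metadata so it is never silent.

`ebic_glasso()` solves the graphical lasso — $\ell_1$-penalized Gaussian
maximum likelihood — by block coordinate descent (compiled code, warm
starts) along 100 log-spaced penalties from $\lambda_{\max}$ (the largest
absolute off-diagonal correlation, at which the model is empty) down to
$0.01\,\lambda_{\max}$, and selects the penalty minimizing the extended
Bayesian information criterion

$$\mathrm{EBIC}_\gamma = -2\ell(\hat K) + E\log n + 4E\gamma\log p,$$

with $E$ the number of estimated edges. The tuning constant $\gamma = 0.5$
is the conventional conservative default in regularized psychometric
network estimation, and that is how this package reads the generic phrase
"threshold tuning parameter of 0.5" that circulates in applied reports: as
the EBIC hyperparameter, not as a post-hoc cut on edge magnitudes. The
alternative reading is still available (`edge_threshold`), but it is off
by default. Estimated weights below `1e-10` in magnitude are stored as
literal zeros so sparsity counts are well defined.

Descriptive edge summaries (`edge_summary()`) follow the reporting
convention of the applied literature: statistics are taken over the unique
off-diagonal weights with zeros included and the age node excluded — age
is a node during estimation (conditioning on it matters) but not part of
the reported network.

## Centrality and the one-SD rule

`node_strength()` sums absolute incident weights; `bridge_strength()` sums
only the absolute weights crossing the boundary of a node's pre-assigned
community, so for every node and any partition

$$s_i = b_i + w_i$$

exactly, where $w_i$ is within-community strength (tested as an exact
identity). Both tables z-score with the sample-SD convention over non-age
nodes and flag a node central when $z \ge 1$; negative z-scores are
computed but never flagged, since negative centrality is not interpreted.
The partition fed to bridge strength comes from Walktrap, not from the
layer labels — the communities are discovered, not imposed — and when an
age node is present its community membership is likewise left to emerge
from the data rather than being forced into a singleton.

## Community detection

`walktrap_communities()` implements agglomerative random-walk clustering:
with transition matrix $P = D^{-1}A$ on absolute weights and walk length
$t = 4$ (the algorithm's conventional default), the distance

$$r_{ij} = \sqrt{\sum_k \frac{(P^t_{ik} - P^t_{jk})^2}{d_k}}$$

drives Ward-style merging of adjacent communities (smallest increase in
mean squared distance), with ties broken by the lowest community-index
pair so that runs are deterministic without any randomness. The dendrogram
is cut at maximum weighted modularity

$$Q = \sum_c \left[\frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2\right],$$

and `modularity_q()` recomputes $Q$ for any partition; the returned $Q$
always equals that recomputation exactly. Absolute values are used because
random walks need non-negative weights; the signed matrix is untouched
everywhere else, and a message notes when negatives were present. $Q \ge
0.5$ is labelled strong evidence of reliable grouping, $[0.3, 0.5)$
moderate, below weak; the two interior cut points are this package's
reading of common applied usage, which labels values near 0.56 strong,
0.39 moderate, and 0.25 weak without stating thresholds. Isolated nodes
become singleton communities. On graphs small enough for exhaustive search
the test suite compares the cut against the true modularity maximum over
all set partitions, and against an independent implementation (igraph).

## Stability

`case_drop_bootstrap()` drops a growing fraction of subjects (grid 0.05 to
0.75 in steps of 0.05 — analyses in this literature report coefficients up
to 0.75, implying a grid that tops out there), re-runs the *entire*
estimation pipeline per replicate, and correlates subsample with
full-sample centralities. Spearman correlation is the default because the
scientific question concerns the rank order of centrality; Pearson is
available. For bridge strength the community partition is re-derived in
every resample, so partition uncertainty propagates into the stability
estimate rather than being frozen at the full-sample solution. The CS
coefficient (`cs_coefficient()`) is the largest grid fraction at which the
correlation stays at or above 0.7 with empirical probability at least
0.95; CS ≥ 0.5 is conventionally called stable. Replicates that fail
(estimation error, undefined correlation) count as below threshold —
conservative by construction, so failures can never inflate CS.
`edge_bootstrap()` provides percentile intervals for edge weights from
subject resampling with replacement; both bootstraps refuse fewer than 100
replicates, and the conventional published analysis uses 2000.

## The synthetic-data generator

The generator is the package's stand-in for a cohort whose raw data are
not shareable, and its defaults *are* the study conditions: behavioral
n = 805 with cortical volume (n = 246) and fractional anisotropy (n = 165)
nested inside it, per-task cell-level MCAR rates matching the published
missing-data percentages (0.12%–9.94% across the ten tasks), and planted
population networks whose non-age edge summaries reproduce the published
single-layer descriptions at two decimals: cognitive mean 0.08, median
0.07, range 0–0.63 with the reading–spelling edge at 0.63 and all others
within [0, 0.27]; cortical volume mean 0.09, median 0, range −0.15–0.52
with the single negative edge between caudal middle frontal gyrus and
frontal pole; fractional anisotropy mean 0.08, median 0, range 0–0.44.
Values not pinned down by those constraints are calibration choices, laid
out to follow plausible domain structure (verbal, fluid, and
working-memory clusters; anatomically neighboring regions and tracts), and
are auditable as plain-CSV fixtures under `inst/extdata/`.

Three generator decisions deserve explicit statement. First, cross-layer
edges in the tri-layer preset are small (|p| ≤ 0.06) and mixed in sign;
no published numbers exist for them, so they are calibration, not ground
truth. Second, the tri-layer age partials are 0.4 times their single-layer
values: a variable's partial correlations legitimately shrink as the
conditioning set triples, and the unattenuated values are incompatible
with a positive-definite 31-node precision matrix. Third, missingness is
MCAR applied after whole-layer nesting — only missingness percentages are
published, not mechanisms, so no MAR/MNAR structure is invented.

What passing tests do *not* show about real data: the generator draws
exact multivariate Gaussians with linear dependencies and MCAR holes. Real
task scores are bounded and skewed, neuroimaging measures carry site and
motion artifacts, and missingness in referred samples is plausibly
informative. Recovery of planted truth here demonstrates the estimators
are implemented correctly, not that the pipeline is robust to those
violations.

## Numerical choices and degenerate inputs

* Glasso convergence: relative tolerance `1e-6` on the working covariance,
  200 outer and inner iterations; non-converged penalties are skipped with
  a warning rather than silently used.
* Exact zeros: the coordinate-descent soft threshold produces literal
  zeros in the precision matrix, which propagate to the weight matrix, so
  "number of edges" is a well-defined integer, not a tolerance question.
* Lasso active sets are not perfectly monotone along the path: a
  coefficient can transiently leave and re-enter near zero. Sparsity is
  therefore monotone only up to single-edge transients, which is how the
  property is tested.
* At very large n the EBIC-selected penalty sits at the path floor and
  admits spurious edges of negligible magnitude (below 0.015 in the
  calibration tests) alongside perfect detection of planted edges ≥ 0.05.
  This is the familiar failure of lasso support recovery without an
  irrepresentable condition, not an implementation defect; summaries that
  include zeros are unaffected.
* Edgeless networks: every node becomes a singleton with Q = 0 and a
  warning; strength tables are all zero with nothing flagged central.
* Zero-variance columns are an error in correlation (never a silent NaN)
  and a logged skip in outlier masking.
* Outlier masking (`mask_outliers()`, default k = 4 SD) recomputes column
  moments on observed cells and reports per-column masked counts;
  `run_sensitivity()` pairs a masked and an unmasked run and emits
  per-edge differences.

## Problem sizes

The shipped tests run the full pipeline at the study's sample sizes
(n = 805/246/165), use n = 50,000–100,000 for law-of-large-numbers and
support-recovery checks, B = 100–400 bootstrap replicates for stability
properties with one deeper regression at B = 200, and exhaustive
modularity search up to 8 nodes — sizes chosen so each property is tested
at a scale where its signal is unambiguous.

## Known limitations

Gaussian marginals only (no nonparanormal or polychoric extensions); MCAR
missingness only; a single estimator family (no mixed graphical models or
directed networks); Walktrap only (no InfoMap/Louvain/consensus
clustering); bootstrap difference tests between specific edges or nodes
are out of scope.
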