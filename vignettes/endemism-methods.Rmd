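---
title: "Methods: spatial phylogenetics of endemism centers and their projected change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial phylogenetics of endemism centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(endemap)
```

`endemap` implements a grid-based spatial-phylogenetics workflow for endemic
floras: alpha-diversity and endemism surfaces with randomization inference
and CANAPE classification, current-to-future change surfaces, dissimilarity
bioregionalization, and spatial-error regression of endemism on environment.
This vignette is the package's account of the science: the models, their
assumptions, the tunable parameters, and the numerical and design choices
behind them.

## Diversity and endemism surfaces

The data model is a rooted phylogeny with branch lengths and, per time
slice, a cells × species presence–absence matrix on a regular grid
(row-major, north-west origin, 0-based ids `r<row>_c<col>`, cell centers as
coordinates; the default cell size is 1000 m).

All metrics are branch-length sums over the edges on the root-paths of the
species present in a cell. Before any metric is computed, both the actual
tree and its *comparison tree* (same topology, all branches equal) are
rescaled to unit total length, so PD and PE read as fractions of the tree
held by a cell and are comparable across trees. Phylogenetic endemism
divides each branch's length by its *range size* — the number of grid cells
reached by at least one descendant tip — concentrating weight on
range-restricted lineages; on an equal-area grid a cell count is the
appropriate range measure. The ratios RPD = PD/PD_comp and RPE = PE/PE_comp
ask whether the branch lengths in a cell are unusually long or short for the
amount of topology present. Conventions worth stating explicitly:

* Root-paths are inclusive of every edge up to the root; no artificial root
  edge is added. This is the standard Faith/Rosauer accounting, and it gives
  an exact conservation identity used as a test oracle: summed unscaled PE
  over cells equals the total length of all represented edges.
* Cells with no species are *no-data*, excluded from every statistic and
  carried as `NA`, never as zero.
* Polytomies are accepted as-is for metric computation; community-level
  metrics are insensitive to their resolution, and `resolve_polytomies()`
  provides seeded random resolutions so `sensitivity_sweep()` can verify
  that insensitivity on any given dataset.
* Unscaled PD/PE (`pd_raw`, `pe_raw`) are emitted alongside the unit-scaled
  values: scaling cancels in RPD/RPE, so only absolute reports differ, and
  both conventions exist in practice.

## Randomization inference and CANAPE

Observed surfaces are ranked against surfaces recomputed on randomizations
of the occurrence matrix that preserve both marginals exactly: cell richness
and species range sizes, the two quantities PE confounds with interest. The
curveball trade algorithm provides uniform sampling of that fixed–fixed
ensemble; the package uses 5 × (number of presences) trades between
successive draws, a standard mixing heuristic, configurable via `n_swaps`.
A matrix that is all ones (or all zeros) has a unique fixed-marginal state
and is returned unchanged with a warning rather than an error.

Percentiles are `(#null < obs + 0.5 · #null = obs) / n_rand`, so a cell
identical to its null sits at 0.5; equality is judged at a 1e-12 absolute
tolerance because the null metrics are floating-point sums. The SES of PD is
`(obs − mean)/sd` over the ensemble, reported as 0 with a `ses_pd_zero_sd`
flag when the null sd vanishes (the sd threshold is relative,
`1e-7 · (|mean|+1)`, to absorb catastrophic cancellation in the running
variance). `n_rand = 999` is the inference-grade default; tests and demos
use 49–199 to stay fast, which coarsens percentile granularity but changes
nothing structurally.

CANAPE is a two-step rule. Step 1 gates on endemism: a cell is considered
only if PE or PE_comp exceeds the 0.975 percentile (the two-tailed cutoff
used throughout; the gate is configurable through `alpha`). Step 2 reads
RPE: above 0.975 → paleo-endemism center (unusually long, old branches),
below 0.025 → neo-endemism center (unusually short, young branches);
otherwise a cell significantly high in *both* PE and PE_comp taken alone is
a mixed center, upgraded to super when both exceed 0.99 (`alpha_super`,
following the originating CANAPE convention; the classification source
quoted only "highly significant"). Cells that pass the gate but meet none
of these conditions are reported `not_significant`; the both-numerator-and-
denominator reading of "mixed" is applied literally. Because published
center counts are sometimes cell counts and sometimes "areas",
`canape_counts()` reports both cells and queen-connected components per
category.

The elevation contrast of center types is a tie-corrected Kruskal–Wallis
test on cell elevations grouped by category; when every elevation is tied
the statistic is reported as 0 with p = 1 rather than NaN.

## Change surfaces

All deltas are signed **future − current**, so negative values are losses —
the sign convention that matches their interpretations (negative ΔSR:
species loss; negative ΔPD: phylogenetic clustering; negative ΔEG: shift
toward specialists; negative ΔBD: biotic homogenization). ΔPD is a
difference of PD standardized effect sizes, so both slices must be run
through the same null configuration. ΔEG always uses *current* niche
breadths for future assemblages — traits are never re-estimated for a
projected slice. ΔBD is the change in a per-cell turnover surface defined
as the mean pairwise βsim between the focal cell and its non-empty
queen-adjacent neighbors (3×3 window by default, radius configurable):
published cell-level βsim maps rarely state their pair set, and a moving
window is the standard construction. Deltas are defined only where both
slices have data.

Driver analysis of a change surface fits additive polynomial-basis linear
models (default cubic per term) for **every** subset of the candidate
predictors, including the intercept-only model, ranked by
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) with k counting all coefficients plus the
error variance. This is an unpenalized stand-in for spline-based additive
models: it preserves the model-selection logic (AICc ranking, deviance
explained) while avoiding a smoothing-penalty implementation, and is the
package's largest deliberate simplification. Fits are refused when
n ≤ k + 1 (AICc undefined).

## Bioregionalization

Cells are clustered in compositional-turnover space. The dissimilarity is
the pairwise phylogenetic βsim matrix over non-empty cells; k-means operates
on its principal-coordinates embedding, CLARA/PAM directly on the
dissimilarity. Numerical notes:

* Min-based turnover is strongly non-metric. The default embedding drops
  non-positive eigenvalues without correction and reports the variance
  represented and the discarded negative magnitude; measured on the
  generator's landscapes, embedding distances rank-correlate with the input
  dissimilarities at roughly 0.66–0.83 even with all positive axes — a real
  information loss, not an implementation artifact. An optional Cailliez or
  Lingoes correction (`correction=` in `compositional_embedding()`) makes
  the embedding essentially exact; note the corrected eigenvalue spectrum is
  flat, so fidelity requires keeping all axes.
* k-means uses multi-start Lloyd iterations (10 starts by default, best by
  within-cluster sum of squares); empty-cluster restarts are discarded
  silently by the multi-start.
* CLARA runs PAM (build + swap) on each of `n_samples` subsamples (default
  5 of size 40 + 2k), scores every candidate medoid set by total
  dissimilarity over *all* cells, and keeps the best; when the sample covers
  the data it reduces exactly to plain PAM.
* The number of sectors is chosen by the mean silhouette over `k_range`
  (default 2–20, bracketing plausible sector counts for a large island
  flora), ties toward smaller k. Results carry a `weak_structure` flag when
  the best mean silhouette is ≤ 0.5: by the usual silhouette reading such
  partitions are weak and possibly artificial — k-means on pure i.i.d. noise
  already reaches widths around 0.4, so "significant-looking" sector maps
  below this band deserve skepticism.

Two regionalizations of the same cells are compared with the V-measure, the
harmonic mean of homogeneity and completeness computed from the label
cross-tabulation; it is invariant to label permutation and weights cells
equally, which on an equal-area grid is area weighting.

## Spatial-error regression

Endemism surfaces are regressed on per-cell environment (elevation, pH,
mean diurnal range, climate stability in the synthetic setting) with a
simultaneous autoregressive error model, u = λWu + ε, which absorbs the
spatial autocorrelation that inflates ordinary least squares. Choices:

* W is a row-standardized k-nearest-neighbor graph on cell centers,
  distance ties broken toward the lower cell index; its eigenvalues are
  computed once per weights object and reused by every fit (the exact
  log-determinant log|I−λW| = Σ log(1−λeᵢ) is cheap at a few thousand
  cells, the package's intended scale).
* Response and predictors are standardized internally — enforced, not
  assumed — so coefficients are comparable effect sizes; λ is invariant to
  this scaling.
* λ is profiled over (−0.999, 0.999) with `stats::optimize`; estimates
  within 0.015 of the bracket raise a boundary warning. `fixed_lambda = 0`
  reduces the fit exactly to OLS, which is the test oracle.
* AICc counts k = p + 2 parameters (all β, λ, σ²). The pseudo-R² is
  Nagelkerke's, `GR² = (1 − exp(−(2/n)(ℓ − ℓ₀))) / (1 − exp((2/n) ℓ₀))`,
  against the intercept-only non-spatial null.
* Model selection (`select_sar_model()`) grids neighbor counts × all
  non-empty predictor subsets, ranks by AICc, and records per-candidate
  failures instead of aborting. Predictors are screened first with
  VIF = 1/(1−R²), flagged at 2 — deliberately strict.
* Residual diagnostics: Moran's I per equal-width distance class (10 by
  default), normal approximation, expectation −1/(n−1); empty or too-sparse
  classes are dropped with a note, and a class containing every pair pins I
  to its expectation with an undefined variance, reported as NA.

## The synthetic landscape: what it emulates, and what it does not

The generator stands in for the inputs a real study would inherit from SDM
stacks and phylogenetic inference. All randomness flows from the config
seed through scoped seeded blocks; identical configs give bit-identical
outputs. Its components and default study conditions:

* **Phylogeny** — Yule pure-birth (rate 1) via `ape::rphylo`. A planted
  signal replaces a random tip with a Yule subclade scaled to 30% of tree
  height and multiplied by `branch_scale` (10 for paleo, 0.1 for neo by
  default): monophyletic by construction, labelled deterministically.
* **Terrain and covariates** — a W–E ridge with four massif-like peaks
  (relief 2400 m by default; 0 gives a flat island); pH, diurnal range and
  climate stability are smoothed random fields explicitly orthogonalized
  against elevation and each other before small couplings (|coupling| ≤
  0.35 sd) are added back, so the covariate set passes a VIF < 2 screen by
  construction rather than by luck.
* **Ranges** — range sizes are 1 + negative binomial (mu 23, size 1.3 by
  default: mean ≈ 24 of 144 cells with a strong right skew, a realistic mix
  of widespread species and narrow endemics — endemism detection is only
  meaningful when planted endemics are *more* restricted than the background
  flora). Placement seeds a cell from a Gaussian elevational-suitability
  kernel and region-grows to the drawn size (queen adjacency), producing the
  spatial cohesion of stacked SDM presences. Niche breadth is tied
  positively to range size (rank-based, 30% noise) inside
  `niche_breadth_range`.
* **Future slice** — each species' optimum moves toward the summit by the
  `future_shift` fraction (default 0.35) of the remaining distance, its
  tolerance narrows by 0.5·shift, and its range contracts by
  min(1, 2·shift·(1−NB)): specialists lose proportionally more, and at
  shift = 1 every specialist (NB < 0.5) is extirpated. Survivors are
  replaced with a sharpened suitability kernel (seeding ∝ suitability⁶,
  growth ∝ suitability²): survivors settle in the best remaining habitat,
  which concentrates upshifted assemblages in the same summit cells and is
  the mechanism producing highland biotic homogenization (negative ΔBD in
  the top elevation quartile). Species with empty contracted envelopes stay
  as all-zero columns — projected local extinctions.
* **Masks** — the protected-area mask covers an exact cell count nearest to
  `pa_fraction` (default 0.4, a typical reserve coverage for a
  well-protected island), biased to high elevation; refugia are cells above
  the 0.75 stability quantile.

What the generator does **not** emulate: realistic climate fields (one
scalar gradient stands in for a climate envelope), dispersal limitation and
biotic interactions, SDM-specific error structure (thresholding artefacts,
spatially autocorrelated prediction error), or multi-model/scenario
ensembles (any number of future slices can be passed through the pipeline,
but none of the ensemble bookkeeping is modelled). Passing tests on this
landscape therefore demonstrates correctness of the *computations* and
directional recovery of *planted* structure — not calibrated realism of any
particular flora.

## Problem sizes and test design

The test-suite study conditions are chosen to exercise every code path in
seconds-to-minutes at desk scale: 12×12 grids with 40 species for pipeline
runs, 10×20 grids for null-calibration (999 randomizations), a 300-cell
lattice with 20 replicates for SAR parameter recovery, 50 random
tree × occupancy instances (≤ 32 tips, ≤ 100 cells) for the conservation
and oracle-equivalence sweeps, and 10 seeded landscapes for planted-signal
recovery at 199 randomizations. Every stochastic test fixes its seed;
properties with sampling variability (type-I rate, recovery rates, coverage
counts) are asserted at the tolerances appropriate to their sampling
distribution (e.g. a binomial 95% interval for the type-I rate).

## Known limitations

* Dense matrices throughout: grids beyond a few thousand non-empty cells
  will be slow (pairwise βsim and the eigendecomposition of W are the
  bottlenecks).
* The driver analysis substitutes unpenalized polynomial additive models
  for penalized splines; deviance-explained values are not comparable to
  spline-based reports.
* The curveball null preserves marginals but not spatial structure within a
  species' range; spatially constrained nulls are out of scope.
* No FDR correction is applied across cells, matching standard CANAPE
  practice; with many cells a few false centers are expected by
  construction.
* Surfaces are exchanged as CSV/TSV keyed by cell id; raster export is
  intentionally out of scope.
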