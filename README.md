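# endemap

Spatial phylogenetics of endemism centers on gridded floras, and how those
centers are projected to change under climate change.

`endemap` is aimed at biogeographers and conservation scientists working with
stacked species-distribution maps of narrow endemics (island floras, mountain
systems) and a dated phylogeny. It answers four linked questions on a regular
grid of cells:

1. **Where are the centers of endemism, and are they old or young?**
   Per-cell phylogenetic diversity and endemism are computed from branch
   lengths, compared against a fixed-marginal randomization null, and
   classified into neo-, paleo-, mixed and super-endemism centers (CANAPE).
2. **How will diversity change?** Current-to-future change surfaces for
   species richness (ΔSR), phylogenetic structure (ΔPD, on standardized
   effect sizes), ecological generalism (ΔEG, from species niche breadths)
   and phylogenetic beta-diversity turnover (ΔBD), with AICc model selection
   over candidate drivers.
3. **How is the region compartmentalized?** Dissimilarity-based
   bioregionalization (k-means / CLARA with silhouette-optimal k), and the
   V-measure to quantify how much the sector map changes between time slices.
4. **What explains the endemism surfaces?** Spatial autoregressive error
   models with VIF screening, AICc-driven neighbor and predictor selection,
   Nagelkerke pseudo-R², and Moran correlograms of residuals.

Because real inputs of this kind (SDM stacks, dated phylogenies, niche
breadths, refugia masks) are rarely redistributable, the package ships a
seeded synthetic-landscape generator that emulates all of them — including
plantable paleo/neo endemism signals and a "future" slice produced by upslope
range shift and contraction — so the entire pipeline is testable end to end.

## The statistics in brief

For a cell with species set *S* on a tree scaled to unit total length:

- **PD** = Σ branch lengths on the root-paths of *S* (Faith, root-inclusive).
- **PE** = Σ (branch length / branch range size), where a branch's range size
  is the number of grid cells holding at least one of its descendant tips.
- **PD_comp, PE_comp**: the same quantities on the *comparison tree* — same
  topology, all branches equal, unit total length. **RPD** = PD/PD_comp,
  **RPE** = PE/PE_comp.
- Significance: each observed surface is ranked against metric surfaces
  recomputed on `n_rand` curveball randomizations of the occurrence matrix
  (row and column sums preserved exactly); two-tailed cutoffs at
  0.975/0.025.
- **CANAPE**: cells significantly high in PE or PE_comp are classified by
  their RPE percentile — high → paleo, low → neo; high in both PE and
  PE_comp alone → mixed, both beyond 0.99 → super.
- **β diversity**: βsor = (b+c)/(2a+b+c) decomposed into turnover
  βsim = min(b,c)/(a+min(b,c)) and nestedness βsne = βsor − βsim, on shared
  (a) and unique (b, c) branch lengths; the per-cell ΔBD surface uses the
  mean βsim to queen-adjacent neighbors.
- **V-measure**: harmonic mean of homogeneity h = 1 − H(A|B)/H(A) and
  completeness c = 1 − H(B|A)/H(B) between two partitions of the cells.
- **SAR error model**: y = Xβ + u, u = λWu + ε, fitted by profile maximum
  likelihood with the exact log-determinant from the eigenvalues of the
  row-standardized k-nearest-neighbor weights W.

## Worked example

```r
library(endemap)

cfg <- landscape_config(
  n_rows = 12, n_cols = 12, n_species = 40, seed = 1,
  planted_signals = list(
    planted_signal(rows = c(1, 3), cols = c(1, 3), "paleo", n_taxa = 4),
    planted_signal(rows = c(8, 10), cols = c(8, 10), "neo", n_taxa = 4)))
land <- simulate_landscape(cfg)
land
#> <landscape> 12 x 12 grid, 40 species, seed 1
#>   planted signals: 2; future_shift: 0.35; extinct in future: 1

sig <- null_significance(land$current, land$tree, n_rand = 199, seed = 12)
centers <- canape_classify(sig)
canape_counts(centers, land$covariates)
#> # A tibble: 6 × 3
#>   category        n_cells n_components
#> 1 neo                   3            2
#> 2 paleo                 8            1
#> 3 mixed                 0            0
#> 4 super                 1            1
#> 5 not_significant     131            1
#> 6 no_data               1            1
```

The planted 3×3 paleo block in the island's north-west is recovered as a
single 8-cell paleo component; the neo block in the south-east yields neo
cells (plus one super cell). Do center types sit at different elevations?

```r
center_elevation_test(centers, land$covariates)
#>   statistic    df p_value n_groups     n
#> 1      8.70     3  0.0336        4   143
```

A tie-corrected Kruskal–Wallis H of 8.70 on 3 df: center types are not
randomly placed along the elevation gradient. The projected future slice
shows highland homogenization (negative turnover change up high):

```r
deltas <- compute_deltas(land$current, land$future, land$tree, land$traits)
summary(deltas$d_bd)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.     NA's
#> -0.26220 -0.07196 -0.00998  0.00391  0.06022  0.37376       37

overlap_percentages(centers, land$masks, "protected")
#>   category        n_cells n_inside pct_inside
#> 1 neo                   3        1       33.3
#> 2 paleo                 8        0        0
#> ...
```

`plot_canape(centers, land$covariates)`, `plot_surface()` and
`plot_regionalization()` draw the corresponding maps; `run_pipeline(cfg)`
executes every stage (metrics → nulls/CANAPE → deltas → bioregions → SAR →
overlaps) and returns a single structured report, optionally writing every
table plus a checksummed manifest to a run directory.

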