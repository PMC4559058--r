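# grainbeta

Beta diversity — the compositional variation among spatially discrete
communities — depends on the *sampling grain*: the size of the unit you
call "one community". Point comparisons between habitats at a single grain
can badly misrepresent how much diversity a landscape actually holds.
`grainbeta` is an R package for ecologists analysing site-by-species
abundance tables (the motivating system is ground-foraging ants in oil
palm and forest landscapes) who want beta diversity quantified *across*
nested sampling grains, with abundance measured as biomass and with honest
uncertainty on every comparison.

## What it computes

The core is the Hill-number family and its multi-assemblage overlap
transformation. For a relative-abundance vector *p*,

    ^qD = (Σ_i p_i^q)^(1/(1−q)),   ^1D = exp(−Σ_i p_i ln p_i)

is the effective number of species of order *q* (*q* = 0: all species,
*q* = 1: common species, *q* = 2: dominant species). For *N* equally
weighted communities, diversity partitions into gamma, alpha and
D_β = D_γ/D_α ∈ [1, N], which is mapped onto [0, 1] as the overlap

    C_qN = [(1/D_β)^(q−1) − (1/N)^(q−1)] / [1 − (1/N)^(q−1)],
    C_1N = 1 − ln(D_β)/ln(N)

— the multi-assemblage Sørensen (*q* = 0), Horn (*q* = 1) and
Morisita–Horn (*q* = 2) indices. Beta diversity is reported as
^qβ = 1 − C_qN.

Around that core the package provides:

- **Data model and I/O** — validated samples × species count/biomass
  matrices, sample metadata, and species trait tables, all as plain CSV.
- **Biomass conversion** — per-species-caste mean dry weights, with
  log–log allometric regressions (body dimension routed by subfamily)
  predicting weights for species with fewer than three weighed specimens.
- **Grain hierarchy** — greedy proximity pairing of plots into pooled
  pairs (grain 2) and pairs-of-pairs (grain 3) under distance caps, with
  omitted plots logged and an explicit-pairing override.
- **Inference** — bootstrap SEs (unit or within-community individual
  resampling), standardized Z tests, and Benjamini–Hochberg FDR control
  per comparison family; singleton-omitted sensitivity reruns.
- **Sampling completeness** — analytic sample-based rarefaction and the
  singleton/doubleton coverage estimator.
- **Synthetic landscapes** — a seeded generator with known species-pool
  overlap, log-series abundances, and a spatial layout that satisfies the
  grain pairing rules, so the whole pipeline is testable against ground
  truth.

## A worked example

```r
library(grainbeta)

truth <- synthetic_truth(n_species_oil_palm = 40, n_species_forest = 60,
                         n_shared = 25, n_plots = c(oil_palm = 8, forest = 8),
                         individuals_per_plot = 300, seed = 42)
cfg <- analysis_config(truth = truth, B_pairwise = 200, B_multi = 200, seed = 42)
report <- run_full_analysis(cfg)

report$summary
#> oil palm: 40 species (total count 2400.0), forest: 60 species (total count 2400.0)
#> 25 shared; union 75; exclusive: oil palm 37.5%, forest 58.3%

subset(report$overlap_table, grain == 2)
#>  grain  habitat q N   CqN   beta      se         scheme
#>      2   forest 0 4 0.925 0.0748 0.01465 resample_units
#>      2 oil_palm 0 4 0.989 0.0108 0.00277 resample_units
#>      2   forest 1 4 0.726 0.2736 0.08331 resample_units
#>      2 oil_palm 1 4 0.805 0.1952 0.05853 resample_units
#>      2   forest 2 4 0.459 0.5409 0.15073 resample_units
#>      2 oil_palm 2 4 0.591 0.4089 0.13089 resample_units

report$pairwise_table[report$pairwise_table$q == 0, ]
#>  grain q mean_similarity      se n_pairs
#>      1 0           0.420 0.01234      64
#>      2 0           0.473 0.00956      16
#>      3 0           0.495 0.01683       4
```

Reading the output: the four grain-2 forest units overlap almost
completely in species identities (C_0N = 0.93) but only 46% in dominant
species (C_2N = 0.46) — beta diversity of dominants (^2β = 0.54) far
exceeds beta of identities, because each block assembles different
dominant species. The mean between-habitat Sørensen similarity rises from
0.42 at single plots to 0.50 at the largest grain: bigger samples capture
more of each habitat's pool, so the habitats *look* more similar at
coarser grains. Z tests with FDR-adjusted decisions for all between-grain
and between-habitat contrasts are in `report$pairwise_contrasts`,
`report$overlap_grain_contrasts` and `report$overlap_habitat_contrasts`.

A thin CLI wraps the same functions:

```sh
Rscript exec/grainbeta simulate --seed 1 --out landscape/
Rscript exec/grainbeta run --seed 1 --counts landscape/counts.csv \
    --metadata landscape/metadata.csv --traits landscape/traits.csv --out report/
```

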