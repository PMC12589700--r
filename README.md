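# conduitscaling

Comparative analysis of xylem vessel and phloem sieve-element anatomy in
woody angiosperms: how conduit diameter, density and lumen fraction scale
with the distance to the stem tip, and how much climate explains once that
internal allometry is removed.

Conduits widen from the stem tip toward the base because transport
resistance accumulates along the path, so the diameter measured on a
cross-section follows the allometry *Y = Y₀ Mᵇ* with *M* the distance to
the tip. Comparative studies that regress anatomy on climate without
removing this trend conflate plant size with environment. This package
implements the full chain needed to separate the two, for analysts working
with species-level anatomical measurements and phylogenies:

- **Trait computation** — equivalent diameter *D = √(4A/π)* per lumen,
  hydraulic diameter *D_H = (ΣD⁴/N)^¼*, median/quartile diameters, conduit
  density and lumen fraction per cross-section.
- **Allometric scaling** — GLS and phylogenetic GLS fits of log trait on
  log distance with Pagel's λ profiled by maximum likelihood, optional
  variance structures, BIC model selection, likelihood-ratio (partial) R²,
  slope comparison by CI overlap, and averaging across candidate trees.
- **Detrending** — residuals from the selected allometry as size-corrected
  trait values.
- **Phylogeny-corrected correlations** — Pearson correlations through the
  evolutionary trait covariance with one jointly maximized λ.
- **Climate PCA** — correlation-matrix PCA of the 19 bioclim variables,
  first three components retained as predictors.
- **Causal path models** — four scenarios (null / indirect / direct /
  full) linking climate, plant size and trait, tested by d-separation with
  per-claim phylogenetic GLS, Fisher's C, and CICc selection across trees.
- **Synthetic data** — generators for trees, climate, and scenario-wired
  traits with stored ground truth, so every stage is testable end-to-end.

## Worked example

Simulate a 150-species study in which climate shapes plant size and traits
follow the size allometry (slope 0.38, phylogenetic residual λ = 0.4), then
recover the allometry by phylogenetic GLS:

```r
library(conduitscaling)

cfg <- simulation_config(n_species = 150, scenario = "indirect",
                         b = 0.38, lambda_true = 0.4, seed = 7)
sim <- simulate_dataset(cfg)
fit <- fit_gls(sim$data$y, sim$data$x,
               pc = brownian_vcv(sim$trees[[1]]),
               species_id = sim$data$species_id)
fit
#> <scaling_fit:pgls> trait: intercept 3.379, slope 0.381 [0.331, 0.430], p = 5.51e-32
#>   n = 150, lambda = 0.176, var = identity, logLik -51.70, AIC 111.39, BIC 123.43
```

The fitted exponent (0.381, 95% CI 0.331–0.430) recovers the generating
slope 0.38: conduit diameter grows roughly with the cube root of
distance-to-tip. `lambda = 0.176` is this replicate's estimate of the
phylogenetic signal left in the residuals. Detrended values are the
residuals from this line — the species' size-corrected trait:

```r
head(detrend(fit), 3)
#> # A tibble: 3 × 3
#>   species_id trait_name residual
#>   <chr>      <chr>         <dbl>
#> 1 sp001      trait         0.356
#> 2 sp002      trait        -0.489
#> 3 sp003      trait         0.323
```

A positive residual means wider conduits than predicted at that
distance-to-tip; these values are what enters the climate correlation and
path-model stages.

## The analysis workflow

The `analysis/` directory holds the study as numbered drivers, each a thin
script over the package functions, writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R    # synthetic study + ground truth
Rscript analysis/02_conduit_traits.R    # raw lumen areas -> trait records
Rscript analysis/03_scaling_allometry.R # GLS/pGLS scaling, BIC selection
Rscript analysis/04_trait_correlations.R# raw vs detrended correlations
Rscript analysis/05_climate_pca.R       # bioclim PCA, first three PCs
Rscript analysis/06_path_models.R       # d-sep tests, Fisher's C, CICc
```

Stage 3 reports, for example, that vessels widen faster than sieve elements
(slopes 0.35 [0.30, 0.41] vs 0.24 [0.20, 0.29], disjoint CIs — generating
values 0.38 and 0.26), and stage 4 that the cross-tissue diameter
correlation collapses once distance-to-tip is removed. `run_all()` performs
the same six stages programmatically on any traits/trees/climate bundle and
writes a provenance manifest with seed and checksums.

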