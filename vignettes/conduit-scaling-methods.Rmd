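---
title: "Methods: conduit allometry, phylogenetic regression and causal path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conduit allometry, phylogenetic regression and causal path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Woody plants transport water through dead xylem vessels and photosynthates
through living phloem sieve elements. Both conduit types widen from the stem
tip toward the base ("tip-to-base widening"): conduit resistance accumulates
along the transport path, and wider conduits at the base compensate for it.
The conduit diameter measured on a stem cross-section is therefore driven
first by the *distance to the tip* of the sampled position, and only
secondarily by the plant's growing environment. Any comparative analysis of
conduit anatomy against climate that ignores this internal allometry risks
mistaking a size artefact for an environmental signal.

`conduitscaling` implements the full analysis chain needed to separate the
two: trait computation from raw lumen measurements, allometric scaling fits
with phylogenetic correction, detrending, phylogeny-corrected trait
correlations, climate dimension reduction, and causal path-model comparison
— together with a synthetic-data generator that reproduces the statistical
structure of such a study with known ground truth, so every stage can be
validated end-to-end.

## Conduit traits

Each measured lumen area $A$ (µm²) is converted to the equivalent circular
diameter $D = \sqrt{4A/\pi}$. Per cross-section we report the median and the
quartiles of the diameter set, plus the hydraulic diameter

$$D_H = \left( \tfrac{1}{N}\sum_i D_i^4 \right)^{1/4},$$

the uniform diameter that would give the same total conductance for the same
conduit count (lumen conductance scales with $D^4$). Conduit density is the
sector count divided by sector area, and the lumen fraction the summed lumen
area over sector area; both are undefined (reported `NA`) when no sector was
delimited, as for branch sieve elements where conductive phloem cannot be
cleanly separated from parenchyma.

Quartiles use linear-interpolation ("type 7") quantiles, the default of
mainstream statistical software. Diameters are in µm, areas in µm²,
distances in m; density is reported in µm⁻². The measurement-protocol
minimum counts (≥ 50 vessels, ≥ 25 sieve elements per section) are enforced
at construction; a `strict = FALSE` switch admits small synthetic fixtures.
Replicate sections of a species are combined by an arithmetic mean of each
trait (and of distance-to-tip) before species-level analysis; the choice is
deliberate and exposed through `species_trait_table(aggregate =)` because
replicate handling is a genuine degree of freedom in such data.

## Allometric scaling by (phylogenetic) generalized least squares

The allometry $Y = Y_0 M^b$ is fit on the log scale: for log trait $y$ and
log distance $x$,

$$y = \beta_0 + b\,x + \varepsilon, \qquad
\varepsilon \sim \mathcal N\!\left(0,\; \sigma^2\, W(\delta)^{1/2} C(\lambda) W(\delta)^{1/2}\right).$$

$C$ is the Brownian covariance of the phylogeny (shared root-to-ancestor
branch length; identity for plain GLS) with Pagel's $\lambda$ multiplying
the off-diagonal entries, so $\lambda = 0$ removes all phylogenetic
covariance and $\lambda = 1$ is the full Brownian expectation. $W$ is an
optional diagonal variance structure driven by the covariate: identity,
power weights $|x|^{2\delta}$, or exponential weights $e^{2\delta x}$.

Numerical choices, all deliberate:

* **Estimation is maximum likelihood throughout** (not REML), so BIC values
  are comparable across covariance and variance structures; BIC counts the
  two coefficients, $\sigma^2$, $\lambda$ when profiled, and each variance
  parameter.
* $\lambda$ is maximized on $[0, 1]$ by bounded scalar optimization
  (tolerance $10^{-6}$), jointly with $\delta$ by L-BFGS-B when a variance
  structure is present; likelihood ties are broken toward the boundary
  nearest 0, so "no signal" is the default claim under a flat profile.
* Standard errors use $\hat\sigma^2 = \mathrm{RSS}/(n - p)$ with $t$
  intervals on the residual degrees of freedom, while the reported
  log-likelihood is exact ML — the same convention as `nlme::gls`, against
  which the fit is verified to machine precision in the test suite.
* Degenerate inputs (constant response, singular design, non-positive-definite
  covariance) raise warnings or errors rather than returning silently.

$R^2$ values are likelihood-ratio coefficients,
$R^2_{\text{lik}} = 1 - \exp\{-\tfrac{2}{n}(\ell_{\text{full}} - \ell_{\text{reduced}})\}$.
The ordinary $R^2$ column compares the fit against its intercept-only
reduction with phylogeny ignored in both; the partial $R^2$ (phylogenetic
fits only) compares against the intercept-only reduction under the same
covariance family with $\lambda$ re-estimated. The reduced-model convention
is stated here because the two are easy to conflate and they answer
different questions (variance explained by distance at all, versus variance
explained by distance given the phylogeny).

Detrended values are response-scale residuals $d_i = y_i - (\hat\beta_0 + \hat b x_i)$:
a positive value means the species' conduits are wider than the allometry
predicts at its distance-to-tip. Two traits are declared to have distinct
scaling exponents when their slopes' 95% intervals are disjoint. Laboratory
consistency screening fits per-laboratory OLS lines (groups of at least six
species) and flags a laboratory when its intercept or slope interval fails
to overlap the pooled model's interval.

Topological uncertainty is handled by replication: every fit runs once per
candidate tree and the arithmetic means of intercept, slope, interval
bounds, $\lambda$ and information criteria are reported, with per-tree fits
retained.

## Phylogeny-corrected correlations

Trait pairs are correlated through the evolutionary variance–covariance
matrix $R = (Y - \mathbf 1\hat a)^\top C(\lambda)^{-1} (Y - \mathbf 1\hat a)/(n-1)$,
where $\hat a$ are generalized-least-squares root states and one *joint*
$\lambda$ for the whole trait set is maximized under the multivariate
Brownian likelihood (trait covariance and root states profiled out
analytically). $r_{ab} = R_{ab}/\sqrt{R_{aa}R_{bb}}$, with two-sided
p-values from the $t$ approximation on $n-2$ degrees of freedom — the
conventional choice; a likelihood-ratio test would be a defensible
alternative, and the approximation is the reason correlation p-values
should not be over-read near the significance boundary. On a star phylogeny
(or $\lambda = 0$) everything reduces exactly to ordinary Pearson
correlation, which the tests assert to $10^{-8}$. Detrended-value
correlations reuse the residuals of each trait's own selected scaling
model.

## Climate dimension reduction

The 19 bioclim descriptors mix °C and mm, so the PCA operates on the
correlation matrix (all variables standardized); eigenvalue fractions are
reported over all 19 components and the first three are retained as climate
predictors. Component signs are fixed so the first variable (annual mean
temperature) loads non-negatively, making outputs stable across
linear-algebra backends. Before path modelling, all analysis columns are
affinely mapped to $[-1, 1]$ (min–max); z-scoring is a plausible
alternative reading of "scaled and centered" and is implemented behind the
same switch (`method = "zscore"`), but min–max is the default because it is
the literal reading and keeps bounded, comparable path coefficients.

## Causal path models

Four directed acyclic scenarios link the three climate components
(PC1–PC3), log distance-to-tip ($x$) and a log trait ($y$). All four share
the climate → $x$ edges, because plant height responds strongly to climate;
they differ in how $y$ is reached: no route (null), through $x$ only
(indirect), directly from climate only (direct), or both (full). The null
scenario keeps its climate → $x$ edges even though no route reaches $y$ —
the trait regressions of the fitted tables carry those coefficients in
every scenario, and dropping them would change the parameter count $q$.

Each scenario is tested by its d-separation basis set: one claim per
non-adjacent vertex pair, conditioned on the union of both vertices'
parents, with the causally downstream vertex as the regression response
(ties broken by node order). Claims among the mutually orthogonal PCs are
retained: orthogonality of scores does not imply independence under a
phylogenetic covariance, so discarding them would be an unstated shortcut.
Claim regressions are phylogenetic GLS with $\lambda$ re-estimated per
regression; a fixed-$\lambda$ mode exists for calibration studies, where
estimating $\lambda$ per claim makes the claim p-values mildly
anti-conservative. Claim p-values combine into Fisher's
$C = -2\sum\ln p_i$ ($\chi^2_{2k}$ under the model) and scenarios are
ranked by $\mathrm{CICc} = C + 2qn/(n - q - 1)$ with $q$ the number of
directed edges. Selection across candidate trees uses the mean CICc, with
per-tree winners logged so topological disagreement stays visible.

A structural caveat that the package's own simulations expose: with $q$
counted as edges, the CICc penalty gaps between the four scenarios (about
6–15 at $n = 150$) are of the same order as the sampling noise of $C$, so
when the data are generated from the null scenario the sparse adequate
models win only about 60% of the time — richer models can absorb noise
claims cheaply. Selection is reliable when effects are strong (the full
scenario is recovered essentially always under path weights ≥ 0.4), and
unreliable for distinguishing nested adequate models. Interpreting a CICc
winner should therefore lean on the coefficient estimates, not the label
alone.

## The synthetic-data generator

The generator is first-class, tested code that produces data with exactly
the structure the analysis assumes: a pure-birth ultrametric tree scaled to
unit depth; in-sample orthogonalized, unit-variance PC scores;
$x = \bar x + \sum_k w_k \mathrm{PC}_k + \epsilon_x$; and
$y = \beta_0 + b\,x + \sum_k v_k \mathrm{PC}_k + \varepsilon_y$ with
$\varepsilon_y$ Brownian on the tree under $\lambda_{\text{true}}$, and $b$
and/or $v$ forced to zero by the scenario. Defaults encode the study
conditions the analysis targets:

* $n = 150$ species, one tree unless replication over topologies is under
  test;
* allometric presets $b = 0.38$ (vessels, intercept 3.44) and $b = 0.26$
  (sieve elements, intercept 2.38) — the fitted main-stem exponents;
* $\lambda_{\text{true}} = 0.4$, the order of phylogenetic signal seen in
  diameter residuals;
* climate-to-height weights $(0.59, 0, 0.4)$, near the fitted path
  coefficients;
* $\bar x$ centred so distances span roughly 0.13–45 m, the sampled height
  range; $\sigma_x = 0.8$ so climate explains roughly a third of the
  variance in log distance; $\sigma_y = 0.35$, which puts the allometry's
  variance explained near 0.6–0.7, matching the reported fits.

The bundled study generator wires climate to the traits *only through
distance-to-tip* (the indirect route), so the marginal trait–distance slope
equals the configured exponent exactly; direct climate effects are
exercised separately in the scenario-selection simulations, because any
direct route confounds the marginal allometric slope upward by
$\sum_k v_k w_k / \mathrm{Var}(x)$. Calibration simulations (the Fisher's C
null-rejection study) draw PC scores i.i.d. rather than orthogonalized:
exactly orthogonal scores make the PC–PC claims degenerate (coefficients
identically zero), which would place probability mass at $p = 1$ and make
the $\chi^2$ reference unattainable by construction.

What the generator deliberately does **not** emulate: measurement error in
lumen outlines, within-species replicate structure with unequal variances,
non-ultrametric or mis-specified trees, correlated residuals between vessel
and sieve traits, and spatially structured climate. Passing tests therefore
demonstrate that the estimators recover the truth *under the model's own
assumptions* — they say nothing about robustness to the violations listed
above.

## Problem sizes and runtime

The validation studies use $n = 150$ species with 200 replicates for slope
and $\lambda$ recovery (mean bias ≤ 0.03, interval coverage 0.90–0.98), 500
replicates for $\chi^2$ calibration of Fisher's C (rejection rate at
$\alpha = 0.05$ within [0.02, 0.09]), and 100 replicates per scenario for
CICc selection rates — sizes at which Monte-Carlo error is small relative
to the acceptance bands while the whole study remains a few minutes of
single-core compute. `scripts/acceptance.R` re-runs all of them from
scratch at any seed.

## Known limitations

* $\lambda$ is searched on $[0, 1]$; trees whose structure admits
  $\lambda_{\max} > 1$ can override the bound, but estimates at the
  boundary are reported as boundary values, not extrapolated.
* The variance-structure candidate set (identity, power, exponential) is
  fixed and recorded in the fit descriptor; other covariates than the
  regression covariate are not searched.
* CICc comparisons between nested adequate scenarios are weakly identified
  (see above).
* Correlation p-values use the $t$ approximation, not a likelihood-ratio
  test.
* Name validation, tree inference and climate raster extraction are out of
  scope; species labels must match tree tips exactly (after whitespace
  trimming).
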