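---
title: "Methods: linking canopy reflectance to soil microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking canopy reflectance to soil microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Canopy reflectance spectra integrate foliar chemistry (pigments, water,
nitrogen, lignin, cellulose) and canopy structure. Those same plant
attributes either feed the soil microbial community directly (litter
quality, root inputs) or co-respond with it to shared soil and climate
gradients. `spectromicrobe` operationalises this causal picture in two
complementary analyses:

1. **Association analysis** on field data: how much microbial variance is
   uniquely vs jointly explained by foliar traits, land cover, soil
   properties and climate+location (variation partitioning with partial
   redundancy analysis), and which specific trait–microbe pairs survive
   conditioning on soil/climate confounders (partial Spearman with
   Bonferroni control).
2. **Predictive modelling**: an ensemble of single-response partial least
   squares regressions (PLSR) mapping preprocessed plot spectra to each
   microbial attribute, with uncertainty from ensemble spread and
   interpretation from regression coefficients and Variable Importance in
   Projection (VIP).

PLSR is the right tool because spectra have hundreds of strongly collinear
bands and far fewer plots than bands; it projects the predictors onto a
few latent components that maximise covariance with the response.

### The PLSR workflow, step by step

Given preprocessed spectra $X$ (plots × wavelengths) and a response $y$:

1. **Outlier screening.** The PLSR fit-and-holdout cycle is repeated 200
   times on random 70/30 splits; each observation accumulates held-out
   absolute errors, and the `floor(0.05 n)` observations with the highest
   mean absolute error are removed. Screening happens before the
   calibration/validation split, matching the published order of this
   workflow family; the alternative (screening inside calibration only) is
   available by calling the stages manually.
2. **Calibration split.** A random 70% calibration / 30% validation
   partition. The validation rows are untouched by screening statistics,
   component selection and ensemble fitting.
3. **Component selection.** For 200 random 70/30 splits of the
   calibration set, a full NIPALS fit records the held-out prediction
   residual error sum of squares (PRESS) at every component count. The
   default selection takes the smallest component count within one
   standard error of the PRESS minimum; the plain arg-min rule is a
   configurable alternative (`rule = "min"`). On synthetic checks the two
   rules selected identical counts; the one-SE rule was kept as the
   default because it is explicitly parsimonious and never selects more
   components than the minimum rule.
4. **Ensemble.** 200 members, each a PLSR with the shared component count
   fitted on an independent random 70% draw of the calibration rows.
   Validation predictions are summarised as member mean ± member SD; the
   SD is the reported uncertainty. Negative predictions are reported
   as-is rather than clipped.
5. **Evaluation.** $R^2$ (squared Pearson correlation, the convention
   that matches a fitted line in an observed-vs-predicted plot),
   Nash–Sutcliffe $R^2$ for transparency, RMSE, NRMSE = RMSE / observed
   range, and bias = mean(predicted − observed).
6. **Interpretation.** Per-wavelength VIP (member mean); a wavelength is
   "informative" when VIP > 1, the natural threshold because each
   member's squared VIPs average to exactly 1. Coefficients are
   summarised as member mean ± SD. Single-index NDVI/NDWI ordinary
   least squares models provide the baseline the ensemble must beat.

Predictors are mean-centred but **not** variance-scaled: vector-normalised
reflectance is already on a common scale, and unit-scaling would inflate
noisy low-reflectance bands relative to real absorption features.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| NDVI threshold | 0.4 (strict `<`) | – | removes sparsely vegetated/shadowed plots whose spectra carry little canopy signal |
| Retained bands | 403–1334, 1450–1785, 1971–2396 | nm | drops detector edges and atmospheric water-vapour windows; closed intervals |
| Buffer diameter | 20 | m | matches the plot area sampled on the ground; pixel centres strictly inside the radius |
| Index bands | NDVI 804/673, NDWI 860/1240 | nm | nearest grid band within 3 nm (the ~5 nm grid makes nominal wavelengths inexact) |
| Rarefaction depth | 5000 | reads | shallower samples are dropped; survivors subsampled without replacement |
| Dominant phyla | top `ceiling(0.10 P)` by mean relative abundance, present in all plots | – | ties broken by total reads, then name |
| Alignment windows | ±60 (soil–image), ±120 (others) | days | inclusive; best year per plot = smallest soil–image gap, ties to the earliest year |
| Outlier screen | 200 runs, 5% removed | – | held-out MAE; removal count is `floor(0.05 n)` |
| Calibration split | 70/30 | – | `floor(0.7 n)` calibration rows |
| PRESS selection | 200 splits, one-SE rule | – | see above |
| Ensemble size | 200 members, 70% subsets | – | enough members for a stable predictive SD |
| Partial-RDA permutations | 999 | – | minimum attainable p = 1/1000 |
| Partial-correlation confounders | pH, soil moisture, MAT, MAP, C:N | – | mutually weakly correlated (|rho| < 0.7) but linked to the remaining soil variables |
| Collinearity cutoff | \|rho\| ≥ 0.7 | – | greedy worst-pair elimination by mean absolute correlation |
| CLR pseudocount | half the smallest nonzero relative abundance | – | multiplicative replacement of zeros |
| NMDS | k = 2, 20 restarts | – | Kruskal stress-1; axes PC-rotated, first nonzero loading positive |

## The synthetic generator

`synth_dataset()` emulates the observational structure the analyses are
built for, with planted, recoverable truth:

* Two latent gradients (climate-like and soil-like) with domain-level and
  plot-level components; a canopy-structure covariate correlated with the
  climate gradient.
* Eight foliar traits, each a unit-variance mixture of the two gradients
  plus an independent component, so the gradients are recoverable from
  the traits (and hence from spectra).
* Spectra = smooth vegetation-like baseline + a structural NIR plateau
  term (0.04 reflectance per SD of structure) − seven Gaussian absorption
  features at 705, 983, 1205, 1520, 1660, 2100 and 2300 nm whose depths
  are linear in their driving traits (sensitivities 0.02–0.03 per SD) +
  heteroscedastic noise (SD 0.005 ≈ 0.5% reflectance). Features sit in
  the retained wavelength windows and away from the NDVI bands so VIP
  recovery is a meaningful test.
* Microbial responses mix a direct trait channel and a shared-environment
  channel, weighted by `confound_weight`; the combined linear predictor
  is standardised and carries exactly `signal_fraction` of the response
  variance in expectation. `signal_fraction = 0` yields pure noise (the
  null case); `confound_weight = 1` yields purely environment-driven
  responses whose trait correlations vanish after conditioning on the
  gradients (the confounding dial).
* Core-level lipid tables spread positive plot-level group abundances
  over the standard biomarker lipids and add truncated Gaussian core
  noise; per-core ASV counts are multinomial draws over softmax logits
  (40% of ASVs loaded on the gradients) with Dirichlet overdispersion
  0.15 and uniform read depths on 3000–50000, so some samples fall below
  the 5000-read filter by construction; ~3% archaeal and ~2% undefined
  ASVs exercise the taxonomic filter.
* Observation dates are jittered around a mid-July image date (soil SD
  25 d, foliar SD 40 d) so a small fraction of plots violates the
  alignment windows.

What it deliberately does **not** emulate: radiative-transfer physics (no
PROSAIL), spatial autocorrelation within domains, atmospheric or BRDF
artifacts, fungal ITS data, and phylogenetic structure among ASVs. Tests
that pass on this generator therefore demonstrate that the *estimators*
recover planted structure under realistic dimensionality, noise and
confounding — not that real canopy spectra predict real microbiomes.

## Numerical and design choices

* **Vector normalisation** uses the Euclidean (L2) norm, the standard
  convention for suppressing brightness/shade variation; indices are
  computed on raw spectra before trimming (they are scale-invariant, and
  the 673/804 nm bands must still be present).
* **F:B ratio membership**: bacteria = Gram-positive + Gram-negative +
  Actinomycetales (Actinomycetales are Gram-positive bacteria); fungi =
  saprophytic + arbuscular mycorrhizal. The biomarker 16:1ω7cis is kept
  with the saprophytic fungi as conventionally reported for this data
  product; the mapping is overridable via `plfa_groups(groups = ...)`.
* **Plot aggregation**: the hierarchical Bayesian plot-averaging model
  used with such data is approximated by closed-form empirical-Bayes
  normal–normal shrinkage (pooled within-plot variance, method-of-moments
  between-plot variance, floored at zero). Every shrunken estimate lies
  between the plot mean and the site mean; `tau2 = Inf` recovers plain
  means. ASV matrices always use simple core averaging.
* **Variation partitioning** computes RDA R² (trace of fitted over total
  sum of squares) for every non-empty subset of predictor groups and
  derives all `2^g − 1` Venn fractions by Möbius inversion; with raw R²
  the fractions plus residual sum to 1 exactly. Fractions are also
  reported with the Ezekiel adjustment (standard in community ecology;
  slightly negative values are legitimate and only floored in a separate
  display column). Unique fractions equal adjR²(all) − adjR²(all minus
  group) and match `vegan::varpart` to 1e-9.
* **Partial-RDA significance** uses the Freedman–Lane scheme: residualise
  response and focal group on the conditioners, permute the
  reduced-model residual rows, re-partial the conditioners out of the
  permuted response, and compare pseudo-F values; p = (1 + #{F* ≥ F}) /
  (1 + n_perm), never zero. The re-partialling step matters: without it
  the test is measurably liberal at n = 60.
* **Partial Spearman** inverts the rank-Pearson correlation matrix; a
  singular matrix caused by the confounders is an error naming them,
  while a pair fully explained by the confounders (degenerate mediation)
  is flagged `NA`.
* **"Location"** in the climate+location group is encoded as
  latitude/longitude columns; each predictor group is collapsed to its
  leading principal components (cumulative variance > 80%) before
  partitioning.
* **Resampling** is linear interpolation (exact for affine spectra, error
  bounded by h²·max|f″|/8 on smooth spectra); no extrapolation.
* **RNG discipline**: every stochastic operation takes a seed and runs in
  a private RNG stream (`withr::with_seed`), leaving the caller's state
  untouched; pipeline stages and ensemble members derive recorded 31-bit
  sub-seeds from one master seed.
* **Boundary semantics**: NDVI removal is strict `<`; kept band ranges
  and alignment windows are inclusive; buffer membership is strict `<`
  radius so ties at exactly the radius are excluded deterministically.

## Problem sizes used in the tests

The parameter-recovery suite runs the full chain on 15-domain × 20-plot
(300-plot) networks with 426 bands, ten seeds for the planted-signal case
(signal fraction 0.8) and ten for the null; permutation-test calibration
uses 500 null replicates at n = 60 with 199 permutations; oracle
equivalence uses 50 random small regression problems and dozens of random
community fixtures. These sizes were chosen as the smallest that give
stable pass/fail behaviour for the properties tested.

## Known limitations

* The shrinkage aggregator is a closed-form stand-in for a full
  hierarchical model; it shares variance estimates across plots and does
  not propagate aggregation uncertainty downstream.
* NMDS axes are sign/rotation-normalised but remain only identifiable up
  to the usual ordination ambiguities across different dissimilarity
  inputs.
* The PLSR ensemble quantifies sampling uncertainty of the calibration
  draw, not structural uncertainty (component count is fixed across
  members).
* Variation partitioning assumes linear (RDA) relationships after the
  chosen transforms; strongly unimodal responses would need a different
  ordination basis.
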