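# spectromicrobe

Canopy reflectance as a window on the soil microbiome.

Soil microbial communities drive nutrient cycling and decomposition, but
surveying them across continents is slow and expensive. Plant canopies
integrate many of the same environmental gradients — and express foliar
traits that both shape and reflect the belowground community — so airborne
imaging spectroscopy of the canopy carries indirect information about the
soil microbiome. `spectromicrobe` is an R implementation of the complete
analysis chain for testing and exploiting that link on NEON-style plot
networks (domains → sites → plots → soil cores):

* **Spectral preprocessing** — circular plot-buffer averaging, wavelength
  resampling onto a common grid, NDVI = (R804 − R673)/(R804 + R673) and
  NDWI = (R860 − R1240)/(R860 + R1240) indices, removal of low-vegetation
  plots (NDVI < 0.4), bad-band trimming (403–1334, 1450–1785,
  1971–2396 nm), and L2 vector normalisation.
* **Microbial response derivation** — PLFA biomarker group sums and the
  F:B and G+:G− ratios; 16S ASV workflows (taxonomic filtering,
  rarefaction to 5000 reads, dominant-phylum relative abundances, ASV
  richness, Bray–Curtis NMDS axes) plus Hellinger and centred log-ratio
  transforms.
* **Plot aggregation and alignment** — core→plot means or empirical-Bayes
  shrinkage, and temporal alignment of soil, foliar and airborne
  observations (±60 d soil-to-image, ±120 d across tables, best year per
  plot).
* **Association statistics** — variation partitioning of microbial
  variance across foliar-trait / land-cover / soil / climate+location
  predictor groups by inclusion–exclusion on (adjusted) RDA R², with
  Freedman–Lane permuted partial-RDA significance tests; Spearman and
  partial Spearman correlation tables with Bonferroni correction;
  collinearity screening.
* **Ensemble PLSR** — the core predictive machinery. For each microbial
  attribute *y* and spectra matrix **X** (plots × wavelengths,
  mean-centred): NIPALS partial least squares; component count chosen by
  the PRESS statistic over 200 random 70/30 splits; 5% outlier screening
  by held-out mean absolute error; a 200-member ensemble fitted on random
  70% draws of the calibration data; per-plot predictive mean ± SD on the
  untouched 30% validation set; R², RMSE, NRMSE = RMSE/range and bias;
  wavelength interpretation via Variable Importance in Projection
  (informative when VIP > 1); NDVI/NDWI linear models as baselines.
* **Synthetic data** — a seeded generator of NEON-like datasets (426-band
  spectra on 380–2500 nm, lipid cores, ASV counts with uneven read depths,
  covariates structured by latent domain gradients) with known ground
  truth, so every stage is testable by parameter recovery without any
  downloads.

## Worked example

Simulate a 300-plot network whose microbial responses carry 80% planted
signal, preprocess the spectra, and model one PLFA attribute:

```r
library(spectromicrobe)

cfg <- synth_config(n_domains = 15, signal_fraction = 0.8, seed = 42)
dat <- synth_dataset(cfg)
dat$spectra
#> <spectra_matrix> 300 plots x 426 bands, 380-2500 nm

ndvi <- compute_index(dat$spectra, "NDVI")
ndwi <- compute_index(dat$spectra, "NDWI")
prepped <- vector_normalize(trim_bands(filter_by_ndvi(dat$spectra)$spectra))
prepped
#> <spectra_matrix> 300 plots x 340 bands, 404.941-2395.25 nm

y <- dat$responses$total_plfa[match(prepped$plot_ids, dat$responses$plot_id)]
fit <- plsr_pipeline(prepped$reflectance, y,
                     indices = list(NDVI = ndvi[prepped$plot_ids],
                                    NDWI = ndwi[prepped$plot_ids]),
                     seed = 1042)
str(fit$metrics)
#> List of 6
#>  $ r2    : num 0.766
#>  $ r2_nse: num 0.762
#>  $ rmse  : num 0.464
#>  $ nrmse : num 0.0932
#>  $ bias  : num -1.13e-06
#>  $ n     : int 86
```

The ensemble explains ~77% of the validation-set variance of an attribute
that carries 80% signal by construction, with an NRMSE of 9.3% of the
observed range and negligible bias; three latent components were selected.
Per-plot predictions come with ensemble uncertainty:

```r
head(fit$predictions, 3)
#>      observed   predicted         sd
#> 1  0.42012391  0.28857836 0.04676772
#> 2 -0.08844067 -0.08212548 0.05594222
#> 3  1.04766058  1.02089183 0.10659497
```

Interpretation recovers the planted chemistry: the maximum-VIP wavelength
(1522 nm) sits on the absorption feature that the generator tied to the
response's dominant trait (1520 nm), and the single-index baselines are
far weaker than the full-spectrum model:

```r
fit$vip$wavelength[which.max(fit$vip$vip)]
#> [1] 1522.31
sapply(fit$baselines, function(b) round(b$metrics$r2, 3))
#>  NDVI  NDWI
#> 0.007 0.301
```

`run_pipeline(pipeline_config(...))` chains every stage — synthesis,
preprocessing, alignment, microbial derivation, variation partitioning and
per-response ensembles — into a single reproducible report keyed to one
master seed.

## Documentation

The methods vignette (`vignettes/spectra-to-microbiome.Rmd`) documents the
statistical model, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the numerical
design decisions.
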