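# wheatcanopy

Estimation of winter-wheat biophysical variables — dry matter (DM, t/ha),
leaf area index (LAI), nitrogen concentration (%N) and nitrogen uptake
(Nupt, kgN/ha), plus their partitioning among the four organ pools (stem,
inferior leaves *Linf*, flag leaf *L1*, ear) — from nadir RGB and six-band
multispectral canopy images (bands 490/550/680/720/800/900 nm,
reflectance-calibrated).

The package is aimed at crop-phenotyping researchers who own dense image
time series but only sparse destructive reference measurements: a field
season typically yields 11–17 acquisition dates per microplot against ~6
reference sampling stages. Everything is testable without field data
through a built-in synthetic trial generator.

## The method

**Semi-supervised pseudo-labeling with growth-curve correction.** Let *n*
be the number of reference measurements and *m* ≫ *n* the number of images.

1. **Model 1** is trained on the *n* labeled images (transfer phase: head
   only, 40 epochs, lr 1e-3; fine-tuning: head + last convolutional block,
   10 epochs, lr 1e-5).
2. Model 1 predicts all *m* images; per microplot, the predictions are
   plotted against thermal time (°C-days) and a growth curve is fitted —
   a cubic smoothing spline for LAI, a cubic polynomial for the other
   variables — under a high smoothing condition.
3. Correction rules are applied: non-negativity, organ values forced to 0
   before the organ appears, proportion vectors renormalized to the
   simplex. Curve values at the acquisition times become corrected
   pseudo-labels **Ypseu**.
4. **Model 2** is retrained from fresh initialization on all *m*
   pseudo-labeled images.

Multi-output heads predict the four organ values at once: softmax
activation for DM/Nupt proportions (rows sum to 1), linear for organ %N.
The loss is a masked, weighted squared error

```
L = (1/|I|) Σ_(i,j)∈I  w_j (y_ij − ŷ_ij)²,
```

where I excludes entries whose true label is 0 (organ not yet present) and
the flag-leaf weight is w_L1 = 20 to match the magnitude of the other
pools. Organ-level absolute values are reconstructed as
`total × proportion`, conserving the total exactly.

Unit identities used throughout: `Nupt = DM × %N × 10` and the nitrogen
nutrition index `NNI = %N / (a · DM^(−b))` with the conventional
winter-wheat critical curve (a = 5.35, b = 0.442, constant below
1.55 t/ha).

A conventional baseline — PLS regression on 20 engineered features (6 band
means over Otsu-segmented plant pixels, 12 vegetation indices, height-map
95th percentile, plant ratio) with sequential backward feature selection
under microplot-grouped 5-fold cross-validation — rides the same pipeline
through a common trainer contract.

## Worked example

A synthetic trial with 5 fertility treatments × 3 replicates, 15
acquisition dates and 6 reference dates (m = 225, n = 90), treatment T02
held out, PLS baseline through the pseudo-labeling pipeline:

```r
library(wheatcanopy)
ds  <- generate_trial(5, 3, 15, 6, render_config("feature"), seed = 1)
ds  <- split_by_treatment(ds, "T02")
res <- run_pipeline(plsr_trainer(), ds, trait = "dm_total", seed = 1)
res$metrics
```

```
  model label_source split    trait     rmse        r2  n
1  plsr        ytrue train dm_total 2.548719 0.9167173 72
2  plsr        ytrue   val dm_total 2.168399 0.8276503 18
3  plsr        ypseu train dm_total 3.014642 0.8834849 72
4  plsr        ypseu   val dm_total 2.684038 0.7359358 18
```

Reading: Model 1 (`ytrue`) reaches validation R² 0.83 on the held-out
treatment; the pseudo-labeled Model 2 (`ypseu`) does **not** improve the
PLS baseline (0.74) — linear models do not benefit from more approximately
labeled data the way the CNN does, which is exactly the contrast the
method predicts. The same pipeline with `cnn_trainer()` on an image-mode
trial shows the opposite pattern (the capacity-limited Model 1 is beaten
by Model 2; see `tests/testthat/test-acceptance.R`, end-to-end pipeline
criterion).

Backward feature selection on the same trial (from
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`):

```
PLS baseline: best CV R2 0.990 with 8 feature(s): brf_680, ndvi, gndvi,
savi, osavi, evi2, mtci, ci_rededge
```

## Layout

- `R/` — dataset assembly and TIFF I/O, synthetic trial generator, canopy
  features, PLS + backward selection, compact CNN (specs, losses, Adam
  training loop), pseudo-label pipeline, metrics/NNI/reporting.
- `src/` — im2col/GEMM convolution forward/backward (RcppArmadillo).
- `inst/cli/wheatcanopy` — `simulate`, `features`, `plsr`, `pseudolabel`,
  `evaluate` subcommands.
- `vignettes/methods.Rmd` — model assumptions, tunable parameters, what
  the synthetic generator does and does not emulate, design decisions.
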