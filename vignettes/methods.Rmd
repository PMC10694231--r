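---
title: "Methods: pseudo-labeling with growth-curve correction for wheat canopy traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-labeling with growth-curve correction for wheat canopy traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatcanopy)
```

## The estimation problem

Destructive reference measurements of wheat biophysical variables — dry
matter (t/ha), LAI, nitrogen concentration (% of dry matter) and nitrogen
uptake (kgN/ha), whole-plant and partitioned among stem, inferior leaves,
flag leaf and ear — are expensive: a trial is sampled at roughly six
phenological stages, while the imaging platform visits every microplot on
11–17 dates per season, several images per visit. Supervised regression
models are therefore label-starved while unlabeled imagery is abundant.

The package implements a two-stage remedy. A first model is trained on the
`n` labeled images. Its predictions on all `m` images of each microplot,
ordered by accumulated thermal time (°C-days), trace an approximate crop
growth curve; because biological trajectories are smooth and largely
monotone, fitting a stiff curve through the predictions and reading
corrected values off the curve removes much of the prediction scatter.
These corrected pseudo-labels then train a second model on all `m` images.

## Model components and assumptions

**Regression network.** The desk-scale backbone `tiny_test_cnn` is four
stride-2 3×3 convolution blocks (16/32/64/64 channels), global average
pooling and a dense head; six-channel multispectral input passes first
through a trainable 1×1 convolution mapping 6→3 channels. Named
large backbones (ResNet50, EfficientNet-B0/B4, input sizes 224/224/380)
are accepted as specifications, but constructing them requires pretrained
weights that are not available offline, and no functionality depends on
them.

**Heads and losses.** Whole-plant traits use a linear single-output head.
Organ proportions of DM and Nupt use a 4-way softmax head, so predictions
live on the simplex by construction. Organ %N uses a 4-way linear head
with *masking*: loss terms whose true label is 0 — the organ does not
exist yet — are excluded, so absent organs cannot drag predictions toward
zero. The proportion loss multiplies the flag-leaf term by 20; the flag
leaf's share is an order of magnitude smaller than the other pools and
would otherwise be ignored by the optimizer. The loss divides by the
*count* of included terms (not the summed weights), so it reduces to plain
MSE when weights are 1 and masking is off; this keeps the loss scale
comparable across masking patterns.

**Training phases.** Transfer (head only, 40 epochs, lr 1e-3), fine-tuning
(head + last convolutional block, 10 epochs, lr 1e-5), then the
pseudo-label stage. For `tiny_test_cnn` two accommodations follow from the
absence of pretrained weights: the frozen trunk is a *fixed random*
feature extractor (random-feature regression — the structural analogue of
a frozen pretrained trunk: Model 1 stays capacity-limited, which is the
regime the pipeline addresses), and the pseudo-label stage reuses the
from-scratch transfer+fine-tune pair, because 30 epochs at lr 1e-5 from a
random initialization trains nothing. The 1×1 channel adapter is newly
initialized, never pretrained, and therefore trainable in every phase —
freezing it would pin a random 6→3 projection. Batch size is 16 (not
specified upstream) and the optimizer is Adam throughout. Augmentation is
independent 0.5-probability vertical/horizontal flips only.

**Growth curves.** LAI is unimodal, so it gets a cubic smoothing spline;
DM, %N and Nupt get a cubic polynomial, which is already stiff and fits
sigmoid-like seasonal trajectories adequately. "High smoothing" is
quantified for the spline as the generalized cross-validation penalty
multiplied by a stiffness factor (default 10) — an interpretation, and a
tunable one. Curves are fitted per microplot and per trait, never pooled
across replicates. Extrapolation beyond the observed acquisition window is
refused; pseudo-labels exist only at observed acquisition times.

**Reference anchoring (resolved open question).** Whether the reference
values themselves join the predictions in the curve fit was genuinely
open. The package includes them, at equal weight (`include_ytrue = TRUE`).
Rationale: the references are the most trusted points on the trajectory,
and a first model trained on few dates interpolates with *systematic* bias
at unseen dates, which a curve fitted to predictions alone absorbs
wholesale. Anchoring measurably reduces pseudo-label error at the
reference dates in the package's own tests. Setting
`include_ytrue = FALSE` restores the predictions-only reading.

**Correction rules.** Negative curve values clip to 0; organ values are
exactly 0 before the organ's appearance thermal time (appearance times
travel with the dataset; in the field they derive from growth-stage
observations); proportion 4-vectors renormalize over the present organs.

**Model 2** restarts from fresh initialization — it never inherits
Model 1's weights — and trains on pseudo-labels at all `m` acquisitions.
The option `overwrite_with_ytrue` substitutes true labels at
reference-matched acquisitions, off by default.

## The engineered-feature baseline

Twenty features per acquisition: six band means over plant pixels
(Otsu-segmented on the 800 nm band), twelve vegetation indices, the height
map's 95th percentile, and the plant ratio. The exact upstream index list
is not published; the default registry implements NDVI, GNDVI, NDRE, SAVI,
OSAVI, EVI2, MCARI, MTCI, CI-green, CI-red-edge, mND-blue and GR —
including the three indices the upstream analysis singles out (MCARI,
mND-blue, GR) — and is user-overridable. Indices are computed from
scene-level plant-pixel mean reflectances, not averaged per-pixel maps;
division guards set an index to 0 (with a message) when its denominator
vanishes, keeping feature matrices finite.

Two numerical choices in segmentation deserve note. Otsu's threshold
maximizes between-class variance over a 256-bin histogram with ties broken
toward the lowest bin. Applied to a *single-class* frame (bare soil, or a
closed canopy), Otsu happily splits the noise in half; `plant_ratio()`
therefore trusts Otsu only when the resulting class means are at least
0.10 BRF apart and otherwise falls back to a fixed 0.35 threshold on the
800 nm band, which cleanly classifies both degenerate frames. A constant
band remains an error.

PLS regression is NIPALS with standardized predictors, 2 components by
default (the usual off-the-shelf setting), capped at the surviving feature
count. Backward selection evaluates every size-(k−1) subset by 5-fold
cross-validated R², with folds fixed once per run and partitioned by
microplot so replicate images never straddle folds. The descent runs to a
single feature and the reported best set is the global argmax over all
visited sets — the "stop at the maximum" reading is a restriction of this
and can never win by more.

## The synthetic trial generator

The generator emulates the statistical structure the method needs, not
field radiometry:

- **Trajectories.** DM logistic in thermal time (asymptote 23 t/ha before
  the treatment factor); LAI logistic-rise × exponential-senescence (peak
  ≈ 6.5, below 10% of peak by season end); %N follows the critical
  dilution form min(4.8, a·DM^(−b)) with a = 5.35, b = 0.442 — the
  conventional winter-wheat values; Nupt = DM × %N × 10 exactly. Treatment
  factors spread over [0.4, 1.2] and multiply the DM asymptote and the
  dilution coefficient, mimicking fertilization contrasts.
- **Design.** One microplot per treatment × replicate; references at ~6 of
  the acquisition dates; lognormal replicate jitter on trajectory
  parameters; multiplicative lognormal measurement noise (CV 5% —
  destructive sampling error scales with magnitude) on references, with
  uptake recomputed so the unit identity holds exactly.
- **Organ schedule.** Stem and inferior leaves present from the start;
  flag leaf appears at 600 °C-days, ear at 1000; shares follow positive
  basis functions renormalized at each time (ear ≈ 60% at maturity), with
  exact zeros before appearance.
- **Rendering (image mode).** Soil background, pseudo-leaf ellipses
  (count ∝ LAI), ear ellipses (count ∝ ear DM pool), a two-class
  reflectance table plus Gaussian noise; leaf green/red-edge/NIR
  reflectance brightens with %N; the height map puts the canopy surface at
  0.95·(DM/25)^(1/3) m. Ellipse draws are sequential at a fixed seed, so
  cover is monotone in LAI by construction. This is deliberately
  low-fidelity procedural art: its only contract is monotone, noisy
  trait→appearance mappings sufficient for learning.
- **Feature mode.** A documented, invertible-in-expectation response:
  band means mix soil and leaf through cover = LAI/(LAI+2); structural
  indices saturate in LAI; MCARI/mND-blue/GR are linear in %N and
  MTCI/CI-red-edge linear in Nupt (red-edge indices track canopy nitrogen
  mass in the field); height = 0.95·(DM/25)^(1/3); plant ratio
  = 1 − e^(−0.6·LAI). Only the height feature depends on DM.

What a green test therefore establishes: the pipeline's machinery —
losses, masking, freezing, curve correction, selection, conservation — is
correct, and the two-stage training improves a capacity-limited model on
data with this temporal structure. What it does not establish: performance
on real canopies, robustness to registration or illumination error, weeds,
lodging, cultivar variation, or any of the field nuisances the generator
deliberately omits.

## Numerical choices and degenerate inputs

- References join acquisitions on the exact (microplot, date) key;
  nearest-date joining is rejected to avoid silent label drift.
- Multiple images per microplot and date are separate training samples
  sharing one label; at prediction time they are averaged (an unbiased
  aggregate; per-image scoring is available through the prediction
  tables).
- BRF is float in [0,1] regardless of the 8-bit on-disk encoding; values
  above 1 clip with a reported count.
- Multispectral standardization statistics carry a provenance tag;
  statistics not computed on the training split are refused, closing the
  validation-leakage path.
- The height percentile uses the linear-interpolation convention (R type
  7); NaN pixels are ignored, an all-NaN map is an error.
- PLS with `n_components` equal to the predictor rank reproduces ordinary
  least squares; a duplicated column leaves *full-rank* predictions
  unchanged, while truncated PLS genuinely re-weights duplicated
  directions — a property of the method, not a bug.
- `r2()` is 1 − SS_res/SS_tot, unbounded below; constant observations are
  an error, not NA.
- An all-masked loss batch yields loss 0 with a warning and a zero
  gradient.
- The minimal TIFF layer (uncompressed, 8-bit unsigned or 32-bit float,
  chunky layout, both byte orders on read) exists because the offline
  toolchain has no image I/O package; it reads what it writes plus
  ordinary baseline TIFFs of that shape.

## Known limitations

- `tiny_test_cnn` with a frozen random trunk gives modest absolute
  accuracy; it exists to exercise the pipeline at desk scale, not to set
  benchmarks. Training all layers (`trainable_scope = "all"`) gives much
  stronger single-model accuracy on the synthetic world but removes the
  label-starved regime the pseudo-labeling stage is designed for.
- One pseudo-labeling round only; no iterative self-training, no
  confidence filtering (the curve correction plays that role).
- The spline stiffness factor and the critical-curve coefficients are
  conventions, exposed as parameters rather than estimated.
- No stereovision, band registration or reflectance calibration: the
  package consumes calibrated inputs.
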