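---
title: "Methods: hyperspectral discrimination of herbicide site of action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral discrimination of herbicide site of action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsisoa)
```

## The problem

Herbicides act on a small set of biochemical targets — their *site of action*
(SOA): photosystem II, the ALS enzyme, EPSPS synthase, and so on. Screening a
candidate compound for a *new* SOA with biochemical assays is slow and
expensive. Plants under herbicide stress, however, change their leaf optical
properties within days, and those changes are herbicide-specific. `hsisoa`
implements a full analysis pipeline that takes line-scan hyperspectral images
of treated plants and classifies the SOA of the applied treatment from the
plant's mean reflectance spectrum, days after treatment (DAT) 1–7.

The pipeline has five stages, each an exported module surface:

1. **Calibration** (`calibrate`): raw digital numbers are converted to
   relative reflectance against dark and white reference frames,
   $R_c = (R_{raw} - R_{dark}) / (R_{white} - R_{dark})$, per pixel and band.
2. **Segmentation** (`make_window`, `rededge_slope_map`, `segment_plant`):
   plant pixels are found by thresholding the least-squares slope of each
   pixel's spectrum over the 680–732 nm red-edge window against a centred
   integer ramp, $con_p = \sum_k lin_k\, x_{p,k} \big/ \sum_k lin_k^2$ with
   $lin = (-m, \dots, m)$; the mask is $con > 7$ on percent-scale
   reflectance.
3. **Extraction** (`mean_spectrum`, `savgol_smooth`): the mean spectrum over
   plant pixels, cropped to 460–975 nm and smoothed with a Savitzky–Golay
   filter (order 1, window 5).
4. **Preprocessing** (`preprocess_chain_fit/apply`): $\log_{10}(1/R)$, then
   multiplicative scatter correction (MSC) against the training-set mean
   spectrum, then mean centering — all fitted on training rows only.
5. **Classification** (`ovo_train`, `predict`, `loo_experiment`,
   `day_to_day`): one-vs-one (OVO) decomposition of the K = 9-class problem
   into 36 binary PLS-DA or SVM models combined by soft voting, validated by
   leave-one-out (LOO) cross-validation within a day and by day-to-day
   transfer.

Exploratory statistics (`ndvi`, `pairwise_ttest`, `band_importance`) sit
beside the classifier: NDVI with Welch t-tests over all treatment pairs, and
random-forest band importance (100 trees, fixed seed 42) for one-vs-all or
pairwise contrasts.

## The synthetic study generator

The instrument data this design comes from are not public, so the package
carries a first-class generator with known ground truth
(`render_scene`, `generate_study`). It emulates:

* a line-scan camera with a 380–1030 nm grid at 1.2 nm (542 bands), dark
  frames near the bottom of the DN range and a per-spatial-line white frame
  from a flat reference board;
* a plant-shaped silhouette (stem plus leaf lobes) of vegetation-like
  reflectance — chlorophyll wells, green bump, steep sigmoidal red edge near
  706 nm, NIR plateau — on a bright flat background;
* the full study design: 8 herbicides $\times$ 16 plants + 32 untreated
  controls per round, 2 rounds (320 samples), 7 daily time points, and 5
  outlier plants turning necrotic at 2 DAT;
* treatment effects as multiplicative Gaussian bumps/dips at
  treatment-specific centres, growing by a per-day severity factor and
  drifting a few nm per day;
* nuisance variation: per-plant endmember jitter, per-spectrum affine
  scatter (what MSC removes), additive band noise, and a smooth day-specific
  drift curve shared by all samples of a day (what breaks day-to-day
  transfer).

All randomness flows from a single root seed; the generator seeds once and
draws in a fixed loop order, so every dataset is reproducible bit-for-bit.

### What the defaults mean — and what passing tests do and do not show

The source study reports no quantitative per-class spectral effect sizes, so
the default effect amplitudes are *placeholders chosen to realise the
acceptance conditions* ("strong effects"): primary bands at 0.26–0.32
relative amplitude, secondary bands near 0.1, against band noise of 0.004
and 5 % multiplicative scatter. Under these conditions the 9 classes are
separable by construction. Passing the recovery tests therefore shows that
the *pipeline machinery* is correct — preprocessing does not leak, the OVO
ensemble and its cross-validation are wired properly, feature selection
finds planted signal — not that real herbicide stress is this separable.
Real spectra differ in ways the generator does not model: no
radiative-transfer leaf optics, no within-plant spatial heterogeneity, no
mixed pixels at leaf edges, and stress chemistry far richer than Gaussian
bumps.

### The reflectance scale and the threshold of 7

The red-edge slope of a spectrum bounded by 100 % reflectance over a
$-m..m$ ramp can never exceed $\approx 150/(2m+1)$ percent per band
($\approx 3.5$ for the default 43-band window), so a threshold of 7 is only
meaningful when calibrated reflectance exceeds 1. That happens naturally
when the reference board is darker than vegetation in the NIR: the
generator's default board reflectance is 0.30 against a 0.92 NIR plateau,
giving plant red-edge slopes near 9 and background slopes near 0.
Calibrated values above 1 are deliberately *not* clipped (clipping would
bias MSC), and segmentation defaults to percent scale; both the scale and
the threshold are arguments, not constants.

## Numerical and design choices

* **Window construction.** The red-edge window takes all bands between the
  nearest grid bands to 680 and 732 nm inclusive; an even-length window is
  trimmed by one band from the high end so the zero-sum symmetric ramp
  exists. On the default 1.2 nm grid this yields 43 bands and a ramp
  $-21..21$; on a coarser ~1.3 nm instrument grid the same rule yields the
  classic 41-band $-20..20$ ramp.
* **Crop boundaries** are inclusive with nearest-band matching, so the
  460–975 nm crop is deterministic under any grid.
* **Savitzky–Golay** uses polynomial order 1, window 5 (`signal::sgolayfilt`);
  interior points are exactly the 5-point moving average, edges are fitted
  one-sidedly, straight lines pass through unchanged.
* **Absorbance** uses base-10 logarithm (chemometric convention); reflectance
  at or below $10^{-4}$ is floored with a warning.
* **MSC reference** is the training-set mean spectrum, frozen into the
  fitted `preprocess_model` and reused unchanged for validation and
  day-to-day data — required for a leak-free train-one-day/test-another
  protocol.
* **PLS-DA** is PLS1 by NIPALS on a {0,1} response, 1–3 latent variables;
  the LV count is chosen by leave-one-out RMSE between the continuous
  prediction and the labels (RMSEcv), ties to the smaller model. The class
  probability is the continuous prediction clipped to [0, 1] — the simplest
  monotone map, declared in the model object.
* **SVM** (via `e1071`) searches linear and RBF kernels over log-spaced
  grids, C in $[10^{-3}, 100]$ and $\gamma$ in $[10^{-6}, 10^{-1}]$, six
  points per axis (6 + 36 candidates), scored by LOO RMSE of calibrated
  probabilities; ties resolve to linear, then smaller C, then smaller
  $\gamma$. Probabilities come from a Platt-style sigmoid fitted on training
  decision values with regularised targets, so separable pairs still yield
  finite, monotone calibrations. A single-candidate grid skips the inner
  cross-validation — this is how the large LOO experiments keep one model
  fit per pair per fold.
* **OVO assembly.** Binary models are trained on pair-restricted rows with a
  pair-fitted preprocessing chain; at prediction time one full-training
  chain transforms the incoming spectrum for all 36 models (a sample's pair
  is unknown, so a single reference spectrum must serve), and each class's
  probability is averaged over its K−1 models. Ties in the soft vote go to
  the earliest class in the canonical order (control first, then the study
  table order).
* **LOO implementation.** Preprocessing is refit inside every fold. Binary
  pair models whose two classes do not include the held-out sample's class
  have training rows untouched by the fold, so they are computed once and
  reused — mathematically identical to refitting the full ensemble per fold
  and the reason 320-fold LOO with 36 pair models stays tractable.
* **Outliers** are flagged per plant and removed across *all* days; variable
  per-day sample counts are tolerated and reports carry observed row sums.

## Problem sizes used in tests and reproduction

The validation suite runs the full default design where the property demands
it — 320 day-1 samples (315 after outlier exclusion) for the LOO and
day-to-day experiments, with a single-candidate linear SVM (C = 10) and a
fixed 2-LV PLS-DA so each of the 320 folds costs eight pair refits — and
deliberately small designs elsewhere: 72-sample single-round studies for the
permutation null, 40-sample two-class studies for band-importance recovery,
and 41-band cubes for the segmentation oracle. Full RMSEcv selection (42 SVM
candidates, 1–3 LVs) is exercised on small two-class problems where the
nested cross-validation is cheap.

## Known limitations

* The generator is phenomenological; none of its effect parameters are
  estimates of real herbicide responses, and accuracy figures on synthetic
  data say nothing quantitative about accuracy on instrument data.
* PLS-DA probabilities are clipped scores, not posterior calibrations;
  soft-vote margins between the two learner families are therefore not
  directly comparable.
* Segmentation applies no morphology, so isolated noisy pixels pass or fail
  the threshold on their own.
* The ENVI reader supports the interleaves and scalar data types the
  pipeline writes (BIL/BSQ/BIP; uint8/int16/int32/uint16/float32/float64,
  little-endian), not the full header zoo of every vendor.
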