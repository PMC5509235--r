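---
title: "Methods: NIR hyperspectral origin tracing with berrytrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR hyperspectral origin tracing with berrytrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind berrytrace, and states plainly what the synthetic data
can and cannot tell you about real instrument data.

## The measurement model

A pushbroom NIR imager records raw counts per scan line; the package's
default geometry is a 320-pixel-wide frame with 256 spectral bands evenly
spanning 874–1734 nm (about 3.4 nm between band centers). Raw counts are
converted to relative reflectance with the white/dark correction

$$R = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}},$$

where the reference frames are `cols x bands` matrices applied identically
to every line, the usual arrangement for a line-scan instrument. Two
deliberate conventions:

* A zero denominator anywhere is an **error that reports the offending
  (col, band) coordinates**. A silent `NaN` would propagate into PCA and
  model fits and surface far from its cause.
* Reflectance values outside [0, 1] (possible under noise) are **kept, not
  clipped**, and can be counted with `reflectance_range_flags()`. Clipping
  would bias derivative spectra, which are central to one of the two
  wavelength-selection routes.

## The synthetic scene generator

The generator exists so that every downstream stage — masking,
segmentation, pixel extraction, PCA, selection, splitting, three model
families — runs and is testable with no external data. It emulates:

* **Endmembers.** Berry reflectance per origin class is a smooth rising
  baseline (0.40 at 874 nm to ~0.53 at 1734 nm) minus Gaussian absorption
  dips at 995, 1200 and 1465 nm (widths 26/38/48 nm, depths
  0.06/0.10/0.16). These are the NIR bands of protein N–H overtones,
  starch/lipid C–H stretches and water in berry tissue. Gaussian dips are
  used because they are smooth, differentiable, and their minima and
  inflection points have closed forms that the tests exploit as oracles.
* **Class structure.** The four origins share one dip set and differ only
  by a small additive offset (0, +0.018, −0.018, +0.032) and a mild
  scaling of dip depths (±5–8%). A single `separation` multiplier scales
  both contrasts: 1 (default) gives classes that overlap in PC score space
  but remain clustered — the regime in which origin discrimination is hard
  enough to be interesting; 0 gives identical classes (a chance-level
  null); ~6 gives nearly separable classes used by the recovery tests.
* **Variability.** Each sample (or rendered object) carries a
  multiplicative scatter factor `N(1, 0.02)` — overall brightness
  differences between berries — plus i.i.d. `N(0, 0.01)` noise per
  pixel/band. The defaults were chosen once as plausible for diffuse
  reflectance of fruit at this band count and held fixed; no within-class
  variance figures are available to calibrate against, only the
  qualitative requirement of overlapping-but-clustered score plots.
* **Scenes.** Berries are non-overlapping filled ellipses (semi-axes 8–14
  px by default) on a flat dark stage of reflectance 0.05. Raw frames are
  built by inverting the calibration equation, so noise-free scenes
  calibrate back to the clean truth cube to machine precision — the
  round-trip identity the tests assert.

What the generator does **not** emulate: illumination gradients, specular
highlights, berry texture, wavelength-dependent sensor response, or
correlated (smooth) spectral noise. Two practical consequences. First,
passing tests demonstrate the correctness of the algorithms, not
instrument-level robustness. Second, because pixel noise here is i.i.d.
across 256 bands, the five leading components of the pixel-wise PCA
capture roughly 60–80% of total variance on synthetic scenes; on real
berry cubes — where pixel variation is dominated by smooth brightness
structure — the same five components capture essentially all of it. The
synthetic figure is therefore reported as-is and is not comparable to
real-data cumulative-variance figures.

## Preprocessing

* **Truncation** to 972–1609 nm keeps the contiguous run from the band
  nearest each endpoint, inclusive — 190 of 256 bands on the default axis.
  An exactly equidistant endpoint resolves *into* the requested window.
* **Moving average** (default window 5 bands) uses shrinking windows at
  the edges, preserving length. The window is a convention; no published
  value existed to adopt.
* **Savitzky–Golay** (default window 9, order 3) delegates to
  `signal::sgolayfilt`; edge points use the polynomial fitted to the
  first/last full window. Derivatives are scaled by the band spacing, so
  second derivatives are in reflectance·nm⁻²; the axis must be
  (approximately) uniform and a >1% spacing variation warns.

## Wavelength selection

PCA is column-mean-centered (no scaling), computed by SVD, with each
loading vector's sign fixed so its largest-magnitude entry is positive —
making selections platform-deterministic.

An "extremum" is a strict interior local peak or valley against both
immediate neighbors. Runs of values equal to within a small relative
tolerance (10⁻⁸ of the curve's magnitude) are treated as plateaus and
contribute their leftmost band; this also guarantees that a numerically
constant curve (e.g. the second derivative of a quadratic) has no extrema.
Edge bands never qualify.

Open design points resolved here:

* The loading threshold is exposed (`|loading| >= threshold`, symmetric in
  peaks and valleys) with default 0 plus a `top_m` cap ranked by absolute
  loading. The pipeline default caps the PCA-loadings selection at 20
  bands — a model-size budget, roughly a tenth of the truncated axis. The
  exact threshold that would reproduce any particular published list is
  unknowable from the literature, so reproducing such lists is treated as
  a calibration exercise, not a correctness gate.
* Second-derivative picking operates on the grand-mean curve by default
  (a per-class union is available) with threshold 0 and no cap: on the
  default study conditions the mean curve has ~15 genuine curvature
  extrema, including one within one band of each absorption center.

## Sample splitting

Kennard–Stone is the classic deterministic max–min procedure on Euclidean
distances of the preprocessed spectra: seed with the two mutually farthest
samples, then repeatedly add the sample maximizing the minimum distance to
the chosen set. It runs within each class (stratified), which is the only
way a 2:1 split of 300 per origin yields exactly 200 calibration samples
per origin. All ties break toward the lexicographically smallest sample
id, so the split is invariant to row order.

One property worth knowing: within-class KS leaves each class's held-out
samples systematically *closer to their own class's calibration points*
than to other classes' (the unchosen points are exactly those near
already-chosen ones). For memorizing classifiers (exact-design RBF,
RBF-kernel SVM) this lifts prediction accuracy a few points above chance
even when the classes are statistically identical. The chance-level null
checks therefore evaluate on independently drawn test sets, where all
three models sit at 25% ± a few points.

## The three discriminant models

All three standardize features by calibration-set statistics (z-score).

* **SVM**: one-vs-one soft-margin RBF-kernel machine (libsvm via `e1071`;
  `g` is libsvm's `gamma`). The `(c, g)` grid defaults to powers of two
  spanning 2⁻⁵–2¹⁰ and 2⁻¹⁰–2⁵ in steps of 2⁵, selected by k-fold
  cross-validation accuracy within the calibration set. Ties take the
  earliest grid point.
* **NN-RBF**: exact-design network, one Gaussian unit per calibration
  sample. The hidden response is `exp(−(0.8326·r/s)²)` — 0.5 at radius
  `r = s` — a convention stated explicitly because "spread" definitions
  differ between toolkits. Output weights (plus a per-class bias) solve
  linear least squares on one-hot targets via the normal equations; a
  singular Gram matrix (common for 800 centers in 190 standardized
  dimensions, where the design approaches all-ones or identity) falls
  back to a 10⁻⁸ ridge and the fit logs how often that happened. The
  spread grid covers 0.1–1 in steps of 0.1 and a coarse 1–100 ladder.
* **ELM**: input weights and biases uniform in [−1, 1] from a seeded
  generator, logistic-sigmoid hidden layer, output weights
  `pinv(H)·T`. The hidden-node count is scanned 1–150 in steps of 1 and
  the smallest count attaining the minimum training misclassification is
  kept. The ceiling is configurable, and a warning fires when the optimum
  sits on it — with 800 calibration samples the training-error criterion
  often pushes toward the ceiling, so the warning is informative, not
  exceptional.

Model selection ("recognition rate") is computed by k-fold (default
5-fold) cross-validation **within the calibration set**: tuning on the
prediction set would leak the held-out data into the model choice. The
criterion and the chosen parameters are recorded in the results.

Evaluation reports the confusion matrix (rows = true class), per-class
accuracies, and the macro-mean — the unweighted average of per-class
accuracies, which is how the "Mean" figure of standard results tables is
defined. Accuracies are written to CSV rounded to two decimals.

## Problem sizes

The default pipeline configuration *is* the study condition: 4 origins ×
300 samples on the 256-band axis, truncated to 190 bands, split 800/400.
A full `run_objectwise` at these sizes (all nine model/feature-set
combinations with their searches) takes on the order of a minute on one
core. The test suite exercises the same code paths at reduced sizes
(tens of samples per class, 40–60 bands, trimmed search grids) chosen so
each property is still informative — e.g. 20-seed recovery runs, 8-seed
null runs with 80-sample test sets — while the whole suite stays fast.

## Known limitations

* The ENVI reader/writer supports only the subset it writes (BSQ,
  float32, little-endian, wavelength list in the header).
* The exact-design RBF network stores all calibration samples; it is
  O(n²) in memory and unsuitable for pixel-level training sets.
* Deposited-table ingestion (`read_spectra_table`) recognizes band
  columns by numeric headers; layouts without wavelength headers need
  manual mapping.
* Synthetic realism limits are listed above; in particular, claims about
  pixel-wise cumulative explained variance do not transfer between
  synthetic and real cubes.
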