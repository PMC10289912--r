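---
title: "Serum SERS classification with a 1D-CNN: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum SERS classification with a 1D-CNN: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Label-free surface-enhanced Raman scattering (SERS) of blood serum gives a
molecular fingerprint of the circulating metabolome: a 1D intensity curve
over Raman shifts of roughly 400–1800 cm⁻¹ in which individual bands
correspond to vibrational modes of serum constituents (amino acids, lipids,
nucleic-acid bases, proteins). Disease-associated metabolic change shifts
the relative band intensities, so a well-calibrated classifier can separate
healthy controls from cancer groups directly from serum spectra, without
any labeled probe. `sersnet` implements the full analysis chain for a
four-group design — healthy controls, bladder cancer (BC), adrenal cancer
(AC) and acute myeloid leukemia (AML), sized 30/30/30/20 samples with five
replicate measurements each — and, because no public serum SERS dataset
accompanies that design, a synthetic-data generator that reproduces its
statistical structure so that every stage is testable end to end.

## Synthetic serum spectra

`simulate_sers()` draws each sample's spectrum as

* a sum of Lorentzian lines (default FWHM 14 cm⁻¹) at the 17 prominent
  serum SERS positions of `peak_lexicon()` (494–1654 cm⁻¹). A Lorentzian is
  the natural Raman line shape; a Gaussian option exists. Base amplitudes
  are fixed plausible relative band strengths with the adenine-dominated
  725 cm⁻¹ band strongest;
* group structure: relative to healthy, each cancer profile multiplies a
  designated peak subset by `1 ± modulation` (default 25%): BC raises
  494/589/639/1135 and lowers 1443; AC raises 531/589/1135 and lowers
  959/1443; AML raises 531/1206/1443 and lowers 1073/1654 (cm⁻¹). The
  directions mirror the reported group differences for this design; the
  25% effect size is a free parameter of the generator, not a claim about
  sera;
* nuisance structure: per-sample amplitude jitter (`amplitude_cv`, default
  10%), one smooth degree-5 polynomial fluorescence baseline (so the
  fifth-order baseline-removal stage can in principle remove it exactly),
  a per-spectrum log-normal gain (`gain_sigma` 0.15) emulating
  spot-to-spot intensity variability, additive white noise
  (`noise_sigma` 0.01 of the unit base amplitude), and clipping at zero
  (intensities are non-negative).

These defaults were chosen once as a realistic regime — jitter well below
the 25% group effect, gain variation large enough that min-max
normalization is genuinely needed — and define the study conditions for
all property tests. What the generator does **not** emulate: instrument
response, cosmic-ray spikes, wavenumber miscalibration, correlated
biological covariance between bands, or between-batch drift. Passing tests
therefore demonstrate correctness of the pipeline's mechanics and its
behavior under the assumed signal model, not clinical performance on real
sera.

## Preprocessing tracks

Two tracks, as in standard chemometric vs deep-learning practice:

* **classical** (for mean-spectra comparison, t-tests, PCA-LDA/PCA-SVM):
  Savitzky–Golay smoothing (window 11 points, order 3 — common practice;
  the method reference gives no values), then iterative modified
  polynomial baseline fitting of degree 5 (fit, clip the working curve to
  the fit, repeat until the working curve changes by < `1e-4` of the
  spectrum range or 100 iterations — non-convergence warns and returns the
  last iterate rather than failing), then per-spectrum min-max
  normalization to [0, 1];
* **deep** (network input): linear resampling to the configured input
  length and per-spectrum min-max normalization only. Whether min-max is
  per-spectrum or global is not specified by the source method; we use
  per-spectrum, which is what actually removes per-sample intensity
  variability. Normalizing a constant spectrum is an error by design (the
  alternative is silent NaNs).

## Split-then-augment

110 samples are randomly partitioned into 5 folds of 22 (stratified by
group by default, giving 6/6/6/4 per fold; remainders of non-divisible
groups go to the least-loaded folds). In rotation *r*, fold *r* is the test
set, the next fold the validation set, the remaining three the training
set. Augmentation happens **after** splitting and independently per
subset: each original spectrum anchors `factor` (default 10, inferred from
the published 66→660 sizes) convex combinations of itself and two other
distinct same-group spectra of the same subset, with uniform-Dirichlet
weights. Convexity keeps every synthetic spectrum inside the pointwise
envelope of its sources, so the group's distribution is maintained while
diversity increases, and the subset-wise construction makes train/test
leakage structurally impossible. The anchor is always the first source:
the degenerate weight vector (1, 0, 0) then reproduces the original
spectra exactly, which pins down an otherwise ambiguous definition of
"random linear combination of three spectra". Min-max normalization is
applied after augmentation, matching the stated order of operations.

## The network

`model_spec()` describes a four-block 1D-CNN: each block is convolution
(stride 1, same padding) → batch normalization → ReLU → max pooling
(window 2, stride 2), with 16/32/64/128 channels and kernels 21/11/5/3 —
large receptive fields first for broad spectral context, small ones last
for individual bands. Pooling alone halves the length, so a 2046-point
input traces 1023 → 511 → 255 → 127 and flattens to 127 × 128 = 16256.
Three fully connected layers follow (FC1/FC2 widths 256/64 by default —
the source figure's widths are not recoverable from text, so these are
configurable), each of FC1/FC2 followed by ReLU, batch normalization and
dropout (p = 0.7). Convolution padding/stride are likewise unstated in the
source; stride-1 same-padding is the unique choice under which pooling
alone reproduces the documented length cascade.

Training (`sers_cnn()`) minimizes class-weighted cross-entropy with
rectified Adam (default lr 1e-4, batch 128, up to 300 epochs; convergence
of the loss is expected by ~200 epochs at that rate). Two weight modes
exist because the verbal description ("divide the number of spectra in
each class by the total") up-weights **majority** classes, contradicting
its stated purpose of countering imbalance: `literal_frequency` implements
the sentence verbatim; the default `inverse_frequency` (N/n_c, mean 1)
implements the purpose. The output layer offers `softmax` (default:
mutually exclusive classes, standard cross-entropy on logits) and a
literal `log_sigmoid` mode (per-class log-sigmoid with weighted NLL;
reported scores are then per-class sigmoids). The epoch with the best
validation accuracy is returned; ties go to the epoch with the lower
training loss, so a long plateau of perfect validation accuracy yields the
most converged parameters rather than the first, barely-fitted ones —
this matters for interpretation stability (below). With a fixed seed and
fixed threading, initialization, shuffling and dropout are fully
reproducible.

The network kernels (convolution as a sum of shifted GEMMs, max pooling)
are compiled code; batch normalization, the fully connected head, losses
and the RAdam update are plain R. All gradients are hand-derived and
checked against central finite differences in the test suite.

## Evaluation

`classification_metrics()` applies the four standard one-vs-rest formulas
per class (accuracy, precision, recall, F1) and reports overall accuracy
as the pooled fraction correct with support-weighted averages of the
per-class metrics (weighted recall is then identically the overall
accuracy — the suite asserts this averaging identity), plus macro
averages. Division-by-zero cases return 0 and are flagged. ROC curves are
threshold sweeps over the unique scores with trapezoidal AUC — equivalent
to the tie-corrected Mann–Whitney statistic, which the tests verify by
exhaustive pair counting — for the four groupings: healthy vs cancer and
each cancer vs its complement. `cross_validate()` pools test predictions
over the five rotations into one confusion matrix (per-rotation reports
are retained; whether the published confusion matrix pools or averages is
unstated). Group difference spectra and per-peak Welch t-tests (the
two-sample test variant is unstated; Welch is the safer default) rank the
most discriminative prominent peaks. PCA-LDA and PCA-SVM baselines fit
PCA on the training split only (20 components, RBF kernel — unstated,
configurable).

## Grad-CAM interpretation and contribution degrees

For a spectrum and a target class, `gradcam()` takes the gradient of the
class logit with respect to the last convolutional block's post-pooling
feature maps (the network's coarsest representation, length 127 for a
2046-point input), averages it along the length dimension to one weight
per channel, and forms the ReLU of the weighted channel sum, linearly
upsampled to the input length and min-max normalized. Gradients are taken
at the logit (standard Grad-CAM practice); dropout is off and batch
normalization uses running statistics, so maps are deterministic.
`group_heatmap()` averages the maps of a group's correctly classified
spectra (a misclassified spectrum's map answers a different class's
"why"; including all spectra is an option) and re-normalizes.

The contribution degree of prominent peak *i* is C_i = S_i / Σ S_i, where
S_i is the trapezoidal area of the heatmap inside the peak's
full-width-at-half-maximum window. The FWHM window is found by locating
the local maximum within ± half the smallest lexicon inter-peak spacing
(10 cm⁻¹ — so neighboring prominent peaks never claim the same maximum)
and walking outward to the interpolated half-maximum crossings, clamped
and flagged at the window edge if no crossing occurs. By construction
Σ C_i = 1 and the table is invariant to rescaling the heatmap. Two window
modes exist because the definition is ambiguous about *which* curve the
FWHM is measured on: `heatmap_peak` (default) measures it on the heatmap
itself; `spectrum_window` measures it on a reference spectrum (for group
tables, the group-mean spectrum). The heatmap's intrinsic resolution is
one block-4 feature cell — 11 cm⁻¹ at input 2046, 22 cm⁻¹ at 1024 —
which is comparable to or wider than the 10 cm⁻¹ search window, so
`spectrum_window`, whose windows are as sharp as the spectra themselves,
is the more reliable mode whenever the input length (and hence feature
resolution) is reduced; the identities above hold for either.

## What interpretation can and cannot recover

Two structural limits of Grad-CAM on spectra are worth stating because
the synthetic experiments expose them clearly. First, evidence by
*absence*: a group defined partly by a lowered band (e.g. a 25% reduction
at 1443 cm⁻¹) cannot produce activation there, so down-modulated peaks do
not rank highly in that group's contribution table. Second, shared
high-amplitude bands: the strongest band in every spectrum (725 cm⁻¹ in
the default profiles) carries large activations for all classes and
therefore leaks into every group's table even though it separates
nothing. Both effects are visible in published group contribution tables
for this kind of pipeline, and both mean that perfect recovery of an
injected discriminative peak set in rank order is not a property the
method has; the acceptance suite asserts the literal recovery property
and documents its failure modes rather than weakening it. On clean
single-marker toys (each class differing at exactly one isolated band),
heatmap maxima do localize to the marker within about one feature cell,
and the marker ranks at the top of the contribution table.

## Problem sizes used by the test and acceptance runs

The package's own test and acceptance runs scale the computation to a
single CPU while keeping the 110-sample, five-fold, factor-10 design
intact: spectra are simulated on the full 2046-point axis, the network
input is resampled to 1024 points, and training uses lr 1e-3 for 20
epochs per rotation (the separable synthetic task reaches a perfect
validation plateau well before that; the default lr 1e-4/300-epoch recipe
is the faithful setting for real-scale work). Bookkeeping, metric-oracle,
Eq.-identity, gradient-correctness and baseline-recovery checks run at
small fixed sizes. Known limitations beyond those already noted: the
iterative polynomial baseline can under-fit baselines that are not
polynomial; min-max normalization ties all intensities to the dominant
band; and determinism across BLAS implementations/thread counts is a
convention, not a guarantee.
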