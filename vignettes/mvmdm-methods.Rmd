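---
title: "Methods: wavelet-domain multidimensional CNN ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-domain multidimensional CNN ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmdm)
```

## The model

`mvmdm` classifies stacks of 2D slices (sagittal structural-MRI volumes, or
phantoms emulating them) into two classes by combining three
subband-specific convolutional networks under a majority vote.

**Preprocessing.** A volume is read with its first stored axis as the slice
axis (no reorientation from NIfTI affines — the pipeline operates on raw
slice stacks), a centred contiguous window of `n_keep` slices (88 in the
full-size profile) is retained, and intensities are min–max normalized per
volume to `[0, 1]`. Normalization is per volume rather than per slice so
that the relative contrast between slices, which the energy feature
encodes, is preserved. The centred window drops an equal number of
low-information end slices from each side; the window start is exposed as a
configuration override because the optimal window is scanner- and
protocol-dependent.

**Wavelet stage.** Each slice is decomposed once by the orthonormal 2D Haar
(db1) filter bank into half-resolution subbands `CA`, `CH`, `CV`, `CD`. On
the 2x2 block `[[a, b], [c, d]]`:

- `CA = (a+b+c+d)/2` — approximation,
- `CH = (a+b-c-d)/2` — horizontal-edge content (variation down the rows),
- `CV = (a-b+c-d)/2` — vertical-edge content (variation across columns),
- `CD = (a-b-c+d)/2` — diagonal detail.

The naming of the two oriented detail subbands is a convention; wavelet
libraries disagree on which index of the separable product is "horizontal".
The package pins the convention above, tests it against a brute-force
block-arithmetic oracle, and the routes are subband-configurable, so a user
who prefers the opposite reading can swap the binding. Orthonormality gives
exact energy conservation (Parseval) and perfect reconstruction for
even-sized images, both asserted in the test suite at `1e-8` relative and
`1e-10` absolute tolerance respectively. Odd sizes are handled by
periodization (wrapping the first row/column) so subbands are always
`ceiling(n/2)`; energy accounting is only exact for even sizes, which both
profiles use.

**Feature routes.** The headline binding is:

- 1D route — per-slice energies of `CD`: the energy of a coefficient image
  is the sum over pixels of its gradient magnitude, computed with central
  differences (one-sided at borders). The gradient operator is configurable
  (`sobel` as the alternative); the choice rescales energies but does not
  reorder classes. Energies are reported unnormalized (raw sums): the
  boxplot scales of such features are arbitrary units, and per-area
  normalization is a display choice, not part of the statistic.
- 2D route — the pixel-wise mean of the subject's `CH` images (mean
  fusion), one image per subject.
- 3D route — the subject's full `CV` stack as a volume.

Any route can be re-bound to any subband for ablation studies.

**Networks.** The three full-size architectures are declared layer by layer
and traced symbolically: unpadded stride-1 convolutions (`out = in - k +
1`), floor max-pooling, batch normalization with 4 parameters per channel
(scale/shift trainable, running mean/variance not), ReLU hidden activations
and a single sigmoid output unit. Tracing reproduces the reference shape
columns and the parameter totals 88,385 / 3,305,089 (448 non-trainable) /
24,957,985 exactly; this is asserted without any training. The output
layer is a sigmoid over one logit: a softmax over a single unit is
degenerate, so the binary probability formulation is the meaningful one.

**Ensemble.** The routes' binary predictions (threshold 0.5 on the sigmoid
probability) are fused by majority vote. Three binary voters cannot tie;
for completeness the vote operation accepts even ensembles and falls back
to thresholding the mean probability, documented as an extension.

**Metrics.** From the confusion matrix with the disease class positive:
accuracy, precision, sensitivity, specificity, and F1 (harmonic mean of
precision and sensitivity), reported as full-precision percentages and
rounded only for display. A metric with a zero denominator is undefined and
reported as `NA`, never coerced to 0.

## The phantom generator

The generator exists so the pipeline's statistical claims are testable
without clinical data. It emulates exactly one property of the application
domain: *the disease class has lower gradient-magnitude energy across its
tissue boundaries*. A subject is a stack of `n_slices` square slices
containing:

- `n_blobs` smooth ellipsoidal blobs (linear boundary ramps, random
  centres/radii/amplitudes) inside an elliptical "head" region, elongated
  along the slice axis so structures span many slices (the 3D route needs
  cross-slice context);
- a fixed-amplitude elliptical rim shared by both classes;
- additive Gaussian voxel noise and a per-subject global intensity factor
  (a scanner-gain surrogate).

For class 1 the blob amplitudes are scaled by `1 - effect`, reducing
boundary intensity gradients — edge contrast — proportionally. The rim is
the design's load-bearing element: per-volume min–max normalization maps
the volume onto `[0, 1]`, and without a class-independent intensity anchor
the amplitude scaling would be exactly undone (a volume scaled by a
constant normalizes to the same result). The rim sets the volume maximum in
both classes, so the class-1 reduction survives normalization. (A variant
that reduced edge *steepness* at constant amplitude was considered and
rejected: widening a boundary ramp spreads the same detail-subband mass
over more pixels, which barely changes the 2D/3D route inputs.)

Defaults (88 slices of 256x256, 8 blobs, noise sd 0.01, edge width 0.18 of
the blob radius, effect 0.5) are fixed once; the scaled test profile used
throughout the suite is 16 slices of 64x64. At `effect = 0` the generator
draws blob geometry before applying the label, so the classes are
exchangeable by construction — the basis of the null-calibration tests.
Per-subject seeds are derived from the cohort seed and subject index by an
integer mix, making cohorts reproducible and subjects independent. Volumes
are written as NIfTI with identity affines.

What the phantom deliberately does not model: anatomy (no tissue classes,
no ROIs), lesions, partial-volume effects, scanner noise physics
(Rician noise, bias fields), or registration error. Passing tests therefore
demonstrate that the pipeline detects class-dependent edge-contrast
differences under controlled conditions — not that it detects schizophrenia
in real cohorts.

## Training numerics

No deep-learning framework is used: the package includes a compact,
deterministic CPU engine. Convolutions and poolings are expressed through
index matrices precomputed per layer (im2col), so passes reduce to dense
matrix products plus one sparse scatter for the convolution backward pass.
Choices that matter:

- **Optimizer** Adam (`lr = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`,
  `eps = 1e-8`), binary cross-entropy, batch size 32, the reference
  training settings.
- **Initialization** Glorot-uniform for all weight matrices, zero biases.
  He-scaled normal initialization was tried first and abandoned: on the
  small 3D route it occasionally produced saturated initial logits followed
  by a dead-ReLU collapse (loss pinned at `ln 2`).
- **Batch normalization** uses batch statistics in training and running
  statistics (momentum 0.9) at evaluation; the relatively fast momentum is
  chosen because scaled-profile runs take only tens of optimizer steps,
  too few for a 0.99 moving average to leave its initialization.
- **Checkpointing** with a validation split (default 20%, stratified)
  retains the epoch with the best validation *accuracy*, ties broken by
  lower validation loss. Validation-loss monitoring was observed to keep
  improving while a run drifted away from a perfectly separating epoch
  into a near-degenerate region, so for a binary classifier accuracy is
  the more faithful monitor.
- **Restarts** A small all-ReLU network can die into a constant-output
  state from an unlucky initialization (every hidden unit inactive for
  every sample leaves no gradient to recover). `train_model()` detects a
  collapsed fit by its accuracy criterion and retrains with a seed derived
  deterministically from the configuration seed, up to two extra attempts,
  keeping the best attempt. This is the usual practical remedy at these
  network and data sizes and does not alter the declared architectures.
- **Determinism** Every stochastic source (initialization, shuffling,
  dropout, splits, fold assignment) derives from the configuration seed
  through R's RNG; identical configurations reproduce identical histories,
  models and reports. The RNG state of the calling session is saved and
  restored around every seeded operation.
- **Standardization** Features are standardized with training-set
  statistics: per-feature for energy vectors, a single global mean/sd for
  image and volume routes (per-pixel standardization would whiten away the
  spatial structure the convolutions exploit).
- **Failure guards** Non-finite losses abort with the epoch and batch;
  single-class training sets and shape mismatches are rejected up front.

**Problem sizes.** The suite and the acceptance script train at the scaled
profile: 60-subject cohorts (40 train / 20 test), 16x64x64 phantoms, 40
epochs. Forty epochs at 40 subjects is roughly 80 optimizer steps — chosen
to give the scaled runs a step budget comparable to full-size training
(hundreds of steps), since 20 epochs at two minibatches per epoch leaves
convergence noticeably init-dependent. The full-size architectures are
validated by symbolic tracing, not by training, which keeps the whole suite
within minutes on one CPU.

## Evaluation harnesses

- `kfold_evaluate()` — stratified k-fold cross-validation repeated over a
  seed list, reporting per-fold metrics and per-seed mean/SD of accuracy;
  the seed-stability analysis at small scale.
- `generalization_run()` — train on one cohort, test on a disjoint cohort
  (subject-id leakage is a hard error), per-route and ensemble metrics with
  confusion matrices; the cross-dataset protocol.
- `run_pipeline()` — simulate/load, decompose, extract, train, vote,
  report; writes metrics (JSON/CSV), confusion matrices, training histories
  and an architecture dump, and is reproducible end to end from one seed.

## Known limitations

- The training engine is sized for the scaled profile; training the
  full-size 3D architecture (25M parameters on 88x128x128 inputs) on a
  desktop CPU is out of scope, and no GPU path is provided.
- The Haar transform is single-level by design; multi-level decompositions
  and other wavelet families (db2/sym2/coif1 appear in ablation protocols)
  are accepted by the configuration surface only insofar as the routes are
  subband-configurable — the filter bank itself is fixed to db1, whose
  halving and orthonormality the pipeline's bookkeeping relies on.
- The frequency-domain ablation filter is an ideal (hard) radial mask;
  ringing is inherent to ideal masks and no windowed variant is provided.
- Phantom realism is intentionally minimal (see above); conclusions about
  real cohorts require real data.
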