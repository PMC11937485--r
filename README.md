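# mvmdm

Max-voting multidimensional CNN ensemble for wavelet-domain classification
of structural-MRI-like volumes.

## The problem

Structural MRI volumes of psychiatric cohorts (e.g. schizophrenia vs
healthy controls) show diffuse, subtle contrast differences rather than a
single focal lesion: gradient magnitudes of pixel intensities tend to be
*lower* across brain regions in the patient group. `mvmdm` implements a
classification pipeline built around that observation, for researchers who
want to reproduce, probe, or extend the approach without access to clinical
data:

1. **Wavelet decomposition.** Every sagittal slice of a subject's volume is
   decomposed by a single-level 2D Haar (db1) transform into four
   half-resolution subbands — approximation `CA` and horizontal / vertical /
   diagonal detail `CH`, `CV`, `CD`. An `88 x 256 x 256` stack becomes four
   `88 x 128 x 128` coefficient stacks.
2. **Three feature routes, one per subband and network dimensionality:**
   - *1D route* — the energy feature. For each slice, the sum of gradient
     magnitudes of the `CD` subband, `E_j = sum |grad CD_j|`, giving one
     length-88 energy profile per subject, classified by a 1D CNN.
   - *2D route* — the pixel-wise mean of the 88 `CH` images (mean fusion),
     one `128 x 128` image per subject, classified by a 2D CNN with batch
     normalization and dropout.
   - *3D route* — the full `88 x 128 x 128` `CV` stack, classified by a
     3D CNN.
3. **Max-voting ensemble (MVMDM).** The three binary predictions are fused
   by majority vote; with three voters a tie is impossible.

The three architectures are declared layer-by-layer and traced symbolically:
unpadded stride-1 convolutions, floor pooling, and exact parameter
bookkeeping reproduce the reference totals 88,385 (1D), 3,305,089 with 448
non-trainable (2D), and 24,957,985 (3D), and flatten widths 1280 / 25088 /
193536 — `check_architecture()` verifies all of it in milliseconds with no
data.

Because clinical volumes cannot ship with a package, `mvmdm` includes a
deterministic **phantom cohort generator**: ellipsoidal "tissue" blobs
inside a fixed-amplitude rim, where the disease class has its blob edge
contrast scaled down by a configurable effect size. The generator reproduces
the statistical structure the pipeline assumes (lower detail-subband
energies in the disease class) so every stage — including training and the
ensemble — is testable end to end.

Everything is tidyverse-shaped: manifests, feature tables, metrics, k-fold
results and training histories are tibbles; fitted models have `tidy()` /
`glance()` methods and `autoplot()`.

## Worked example

```r
library(mvmdm)

# a 60-subject phantom cohort at the scaled test profile:
# 16 slices of 64x64, disease class with 60% reduced edge contrast
res <- run_pipeline(
  out_dir  = tempfile("mvmdm_run"),
  simulate = list(n_per_class = 30, n_slices = 16, slice_size = 64,
                  effect = 0.6),
  cfg      = train_config(epochs = 40, seed = 11, validation_split = 0.2),
  profile  = "test",
  test_fraction = 1/3,
  seed     = 11
)
res$metrics
#> # A tibble: 4 × 6
#>   model  accuracy precision sensitivity specificity    f1
#>   <chr>     <dbl>     <dbl>       <dbl>       <dbl> <dbl>
#> 1 1D-CNN      100       100         100         100   100
#> 2 2D-CNN      100       100         100         100   100
#> 3 3D-CNN      100       100         100         100   100
#> 4 MVMDM       100       100         100         100   100
```

The cohort is split stratified into 40 training and 20 held-out subjects;
all three routes separate the classes perfectly at this effect size, and
the majority vote preserves that. At `effect = 0` the classes are
exchangeable and held-out accuracy drops to chance — the pipeline's null
calibration.

Individual stages are exported too:

```r
cfg <- phantom_config(n_slices = 16, slice_size = 64, effect = 0.6)
sv  <- normalize_volume(generate_subject(label = 1, cfg, subject_seed = 7))
sb  <- decompose_volume(sv)          # CA/CH/CV/CD stacks, 16 x 32 x 32
e   <- energy_vector(sb$CD)          # 16 per-slice energies
fused <- mean_fusion(sb$CH)          # one 32 x 32 image

check_architecture()                 # shape/parameter trace vs reference
compute_metrics(list(TN = 73, FP = 1, FN = 0, TP = 71))
#> accuracy 99.31, precision 98.61, sensitivity 100, specificity 98.65, f1 99.30
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "mvmdm.R", package = "mvmdm")` with subcommands
`check-architecture`, `simulate`, `features` and `run`.

## Vignette

`vignettes/mvmdm-methods.Rmd` documents the model and its assumptions, the
phantom generator's design (what it emulates and what it deliberately does
not), the training engine's numerics, and known limitations.
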