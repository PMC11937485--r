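#' Configuration for the phantom cohort generator
#'
#' Bundles and validates the parameters of the synthetic subject generator.
#' The phantom emulates the statistical structure the classification pipeline
#' assumes: stacks of sagittal slices containing smooth ellipsoidal "tissue"
#' blobs inside a fixed elliptical rim, where the disease class (label 1) has
#' its blob edge contrast — the intensity gradient across blob boundaries —
#' scaled down by `1 - effect`. Reduced edge contrast lowers the
#' gradient-magnitude energy of the detail subbands, reproducing the lower
#' energies observed in the schizophrenia class. The rim has a fixed
#' amplitude in both classes and sets the volume's intensity maximum, so the
#' class-1 contrast reduction survives per-volume min-max normalization.
#'
#' @param n_slices Number of slices per subject (default 88, the full-size
#'   profile; the scaled test profile uses 16).
#' @param slice_size Pixels per (square) slice side; must be even so that the
#'   wavelet subbands are exactly half size (default 256; test profile 64).
#' @param effect Relative reduction of class-1 blob edge contrast, in
#'   `[0, 1]`. 0 makes the classes exchangeable.
#' @param noise_sd Standard deviation of additive Gaussian voxel noise.
#' @param n_blobs Number of ellipsoidal blobs per subject.
#' @param edge_width Blob boundary ramp width as a fraction of the blob
#'   radius (same in both classes).
#' @param rim Logical; include the fixed-amplitude outer rim shared by both
#'   classes (the intensity anchor for normalization).
#' @param seed Integer seed associated with the configuration.
#' @return An object of class `phantom_config` (a validated named list).
#' @export
phantom_config <- function(n_slices = 88L, slice_size = 256L, effect = 0.5,
                           noise_sd = 0.01, n_blobs = 8L, edge_width = 0.18,
                           rim = TRUE, seed = 1L) {
  n_slices <- as.integer(n_slices)
  slice_size <- as.integer(slice_size)
  if (n_slices < 1L) stop("`n_slices` must be >= 1", call. = FALSE)
  if (slice_size < 4L) stop("`slice_size` must be >= 4", call. = FALSE)
  if (slice_size %% 2L != 0L) {
    stop("`slice_size` must be even: each wavelet subband is half the slice ",
         "size, so odd sizes cannot be halved exactly", call. = FALSE)
  }
  if (!is.numeric(effect) || effect < 0 || effect > 1) {
    stop("`effect` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (n_blobs < 0) stop("`n_blobs` must be >= 0", call. = FALSE)
  if (edge_width <= 0 || edge_width > 1) {
    stop("`edge_width` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_slices = n_slices, slice_size = slice_size, effect = effect,
         noise_sd = noise_sd, n_blobs = as.integer(n_blobs),
         edge_width = edge_width, rim = isTRUE(rim), seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> ", x$n_slices, " slices of ", x$slice_size, "x",
      x$slice_size, ", effect ", x$effect, ", noise sd ", x$noise_sd,
      ", ", x$n_blobs, " blobs\n", sep = "")
  invisible(x)
}

# deterministic 32-bit mix of cohort seed and subject index
subject_seed <- function(cohort_seed, index) {
  s <- (as.double(cohort_seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483647)
}

#' Generate one phantom subject volume
#'
#' Draws a deterministic phantom volume for one subject: `n_blobs` smooth
#' ellipsoidal blobs at random positions inside an elliptical "head" region,
#' an optional fixed-contrast outer rim, additive Gaussian noise and a
#' per-subject global intensity factor (scanner-gain surrogate; removed again
#' by [normalize_volume()]). For `label = 1` the blob amplitudes — and with
#' them the boundary intensity gradients, the edge contrast — are scaled by
#' `1 - effect`, lowering every gradient-magnitude energy feature
#' monotonically in `effect`; the fixed-amplitude rim anchors the intensity
#' range so normalization cannot rescale the reduction away.
#'
#' Two calls with identical arguments produce identical volumes. Blob
#' geometry is drawn before the label is applied, so at `effect = 0` the two
#' classes are exchangeable.
#'
#' @param label Class label, 0 (healthy) or 1 (disease).
#' @param cfg A [phantom_config()].
#' @param subject_seed Integer seed for this subject's draws.
#' @return A [subject_volume()] with data of shape
#'   `(n_slices, slice_size, slice_size)`, values in `[0, 1]`.
#' @export
generate_subject <- function(label, cfg = phantom_config(), subject_seed = 1L) {
  if (!inherits(cfg, "phantom_config")) {
    stop("`cfg` must be a phantom_config", call. = FALSE)
  }
  if (!(length(label) == 1L && label %in% c(0, 1))) {
    stop("`label` must be 0 or 1", call. = FALSE)
  }
  n <- cfg$n_slices
  s <- cfg$slice_size
  old <- .Random.seed_guard(subject_seed)
  on.exit(old(), add = TRUE)

  # normalized coordinates in [-1, 1]
  z <- if (n > 1L) seq(-1, 1, length.out = n) else 0
  y <- seq(-1, 1, length.out = s)
  x <- seq(-1, 1, length.out = s)

  vol <- array(0, dim = c(n, s, s))

  contrast <- if (label == 1) 1 - cfg$effect else 1

  if (cfg$n_blobs > 0L) {
    for (b in seq_len(cfg$n_blobs)) {
      ctr <- stats::runif(3, -0.45, 0.45)
      rad <- stats::runif(3, 0.14, 0.20) * c(2, 1, 1)  # elongated in slice axis
      amp <- stats::runif(1, 0.40, 0.50) * contrast
      dz <- (z - ctr[1]) / rad[1]
      dy <- (y - ctr[2]) / rad[2]
      dx <- (x - ctr[3]) / rad[3]
      d2 <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
      d <- sqrt(d2)
      ramp <- pmin(pmax((1 - d) / cfg$edge_width, 0), 1)
      vol <- vol + amp * ramp
    }
  }

  if (cfg$rim && cfg$n_blobs > 0L) {
    # fixed-amplitude elliptical shell, identical in both classes: it sets the
    # volume's intensity maximum, anchoring min-max normalization so that the
    # class-1 blob contrast reduction is not rescaled away
    dz <- z / 0.95
    dy <- y / 0.85
    dx <- x / 0.85
    d <- sqrt(outer(outer(dz^2, dy^2, "+"), dx^2, "+"))
    shell <- exp(-((d - 0.95) / 0.12)^2)
    vol <- vol + shell
  }

  gain <- stats::runif(1, 0.9, 1.1)
  vol <- vol * gain
  if (cfg$noise_sd > 0) {
    vol <- vol + stats::rnorm(length(vol), sd = cfg$noise_sd)
  }
  vol <- pmin(pmax(vol, 0), 1)

  subject_volume(vol, subject_id = NA_character_, label = label,
                 source_shape = dim(vol))
}

# seed the RNG restoring previous state on exit; returns restore closure
.Random.seed_guard <- function(seed) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = env) else
      rm(".Random.seed", envir = env)
  }
}

#' Generate a labelled phantom cohort on disk
#'
#' Writes `2 * n_per_class` phantom subjects (balanced classes) as NIfTI
#' volumes under `dir` and returns the cohort manifest. Per-subject seeds are
#' derived deterministically from the cohort seed and subject index, so the
#' cohort is reproducible while subjects are independent. Volumes are stored
#' with an identity affine; orientation metadata is ignored throughout.
#'
#' @param n_per_class Subjects per class (>= 1).
#' @param cfg A [phantom_config()].
#' @param dir Output directory (created if needed).
#' @param seed Cohort seed; defaults to `cfg$seed`.
#' @param dataset_tag Tag recorded in the manifest's `dataset` column.
#' @param write_manifest If `TRUE`, also write `manifest.csv` under `dir`.
#' @return A tibble with columns `subject_id`, `path`, `label`, `dataset`.
#' @export
generate_cohort <- function(n_per_class, cfg = phantom_config(),
                            dir = tempfile("cohort"), seed = cfg$seed,
                            dataset_tag = "phantom", write_manifest = TRUE) {
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  labels <- rep(c(0L, 1L), each = n_per_class)
  ids <- sprintf("%s_%03d_L%d", dataset_tag, seq_along(labels), labels)
  paths <- file.path(dir, paste0(ids, ".nii.gz"))
  for (i in seq_along(labels)) {
    sv <- generate_subject(labels[i], cfg, subject_seed(seed, i))
    RNifti::writeNifti(RNifti::asNifti(sv$data), paths[i])
  }
  manifest <- tibble::tibble(subject_id = ids, path = paths,
                             label = labels, dataset = dataset_tag)
  if (write_manifest) {
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  }
  manifest
}
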