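#' Gradient magnitude of an image
#'
#' Computes `sqrt(Gx^2 + Gy^2)` where `Gx`, `Gy` are finite-difference
#' derivatives: central differences in the interior and one-sided differences
#' at the borders (the default, via [pracma::gradient()]), or 3x3 Sobel
#' derivatives with replicated borders. The operator choice rescales the
#' energy feature but does not change the ordering between classes.
#'
#' @param image A numeric matrix with both dimensions >= 2.
#' @param method `"central"` (default) or `"sobel"`.
#' @return A non-negative matrix of the same shape.
#' @export
gradient_magnitude <- function(image, method = c("central", "sobel")) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(image) < 2 || ncol(image) < 2) {
    stop("`image` must be at least 2x2 for finite differences", call. = FALSE)
  }
  if (method == "central") {
    g <- pracma::gradient(image)
    sqrt(g$X^2 + g$Y^2)
  } else {
    sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
    gx <- conv2_same(image, sx)       # derivative across columns
    gy <- conv2_same(image, t(sx))    # derivative down rows
    sqrt(gx^2 + gy^2)
  }
}

# 3x3 "same" correlation with replicated borders
conv2_same <- function(image, kernel) {
  h <- nrow(image)
  w <- ncol(image)
  pad <- image[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (i in 1:3) {
    for (j in 1:3) {
      out <- out + kernel[i, j] * pad[i:(i + h - 1), j:(j + w - 1)]
    }
  }
  out
}

#' Energy of a subband slice
#'
#' The energy feature of a coefficient image: the sum over all pixels of its
#' [gradient_magnitude()]. It is zero iff the slice is constant and
#' positively homogeneous (`slice_energy(c * X) = c * slice_energy(X)` for
#' `c > 0`). Applied to the diagonal-detail (CD) subband this is the
#' descriptor that separates the classes: reduced edge contrast lowers it.
#'
#' @param cd_slice A numeric matrix (typically one CD subband slice).
#' @inheritParams gradient_magnitude
#' @return A single non-negative number.
#' @export
slice_energy <- function(cd_slice, method = c("central", "sobel")) {
  sum(gradient_magnitude(cd_slice, method = match.arg(method)))
}

#' Per-slice energy profile of a subband volume
#'
#' Computes [slice_energy()] for every slice of a subband coefficient stack,
#' giving the per-subject energy profile (one value per retained slice; 88 in
#' the full-size `"paper"` profile) that feeds the 1D route.
#'
#' @param cd_volume A 3D array `(n_slices, h, w)` — typically the `CD`
#'   element of [decompose_volume()] — or a `subband_volumes` object, in
#'   which case its CD stack is used.
#' @param n_expected If not `NULL`, error unless the slice axis has exactly
#'   this length.
#' @inheritParams gradient_magnitude
#' @return A numeric vector of length `n_slices`, all entries >= 0.
#' @export
energy_vector <- function(cd_volume, n_expected = NULL,
                          method = c("central", "sobel")) {
  if (inherits(cd_volume, "subband_volumes")) cd_volume <- cd_volume$CD
  if (!(is.array(cd_volume) && length(dim(cd_volume)) == 3L)) {
    stop("`cd_volume` must be a 3D array", call. = FALSE)
  }
  n <- dim(cd_volume)[1]
  if (!is.null(n_expected) && n != n_expected) {
    stop("expected ", n_expected, " slices, got ", n, call. = FALSE)
  }
  method <- match.arg(method)
  vapply(seq_len(n), function(j) slice_energy(cd_volume[j, , ], method),
         numeric(1))
}

#' Mean fusion of a subband stack
#'
#' Pixel-wise arithmetic mean across the slice axis, collapsing a subject's
#' per-slice horizontal-detail (CH) images into one fused image for the 2D
#' route. The fusion is invariant to slice order and bounded per pixel by the
#' stack's min and max.
#'
#' @param ch_volume A 3D array `(n_slices, h, w)` or a `subband_volumes`
#'   object, in which case its CH stack is used.
#' @return A numeric matrix `(h, w)`.
#' @export
mean_fusion <- function(ch_volume) {
  if (inherits(ch_volume, "subband_volumes")) ch_volume <- ch_volume$CH
  if (!(is.array(ch_volume) && length(dim(ch_volume)) == 3L)) {
    stop("`ch_volume` must be a 3D array", call. = FALSE)
  }
  if (dim(ch_volume)[1] < 1) stop("empty slice stack", call. = FALSE)
  apply(ch_volume, c(2, 3), mean)
}

#' Extract the three route inputs for one subject
#'
#' Runs the subband-to-route binding on a decomposed subject: the energy
#' profile of one subband (1D route), the mean-fused image of another (2D
#' route), and a full subband stack (3D route). Defaults follow the headline
#' binding CD -> 1D, CH -> 2D, CV -> 3D; any other binding can be selected
#' for ablation.
#'
#' @param subbands A `subband_volumes` object from [decompose_volume()].
#' @param binding Named character vector mapping routes to subbands, e.g.
#'   `c(d1 = "CD", d2 = "CH", d3 = "CV")`.
#' @inheritParams gradient_magnitude
#' @return A list with `energy` (numeric vector), `fused` (matrix), `volume`
#'   (3D array), `subject_id` and `label`.
#' @export
subject_features <- function(subbands,
                             binding = c(d1 = "CD", d2 = "CH", d3 = "CV"),
                             method = c("central", "sobel")) {
  stopifnot(inherits(subbands, "subband_volumes"))
  if (!all(c("d1", "d2", "d3") %in% names(binding)) ||
      !all(binding %in% c("CA", "CH", "CV", "CD"))) {
    stop("`binding` must map d1, d2, d3 to subbands CA/CH/CV/CD",
         call. = FALSE)
  }
  list(
    energy = energy_vector(subbands[[binding[["d1"]]]],
                           method = match.arg(method)),
    fused = mean_fusion(subbands[[binding[["d2"]]]]),
    volume = subbands[[binding[["d3"]]]],
    subject_id = attr(subbands, "subject_id"),
    label = attr(subbands, "label")
  )
}

#' Energy feature table for a cohort
#'
#' Loads every subject in a manifest, decomposes it, and returns the 1D-route
#' energy features as a tibble with one row per subject and one column per
#' retained slice (`e_1 ... e_n`), ready for [train_model()] or export.
#'
#' @param manifest A manifest tibble as from [generate_cohort()] or
#'   [read_manifest()].
#' @param n_keep Number of slices retained per subject (default 88).
#' @param subband Which subband's energies to tabulate (default `"CD"`).
#' @inheritParams gradient_magnitude
#' @return A tibble with columns `subject_id`, `label`, `e_1` .. `e_n`.
#' @export
cohort_energy_features <- function(manifest, n_keep = 88L, subband = "CD",
                                   method = c("central", "sobel")) {
  method <- match.arg(method)
  rows <- purrr::pmap(
    list(manifest$subject_id, manifest$path, manifest$label),
    function(id, path, label) {
      vol <- load_subject(path, subject_id = id, label = label,
                          n_keep = n_keep)
      sb <- decompose_volume(vol)
      e <- energy_vector(sb[[subband]], method = method)
      tibble::tibble(
        subject_id = id, label = label,
        !!!stats::setNames(as.list(e), paste0("e_", seq_along(e)))
      )
    }
  )
  dplyr::bind_rows(rows)
}
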