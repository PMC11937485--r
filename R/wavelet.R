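#' Single-level 2D Haar (db1) wavelet decomposition
#'
#' Decomposes a 2D image into the four first-level subbands of the orthonormal
#' Haar (db1) filter bank: the approximation image `CA` and the horizontal
#' (`CH`), vertical (`CV`) and diagonal (`CD`) detail images. For an even-sized
#' `H x W` input each subband is exactly `H/2 x W/2` and the transform is
#' orthonormal, so it conserves energy (Parseval) and is exactly invertible by
#' [haar_idwt2()].
#'
#' Orientation convention: `CH` carries horizontal-edge content (intensity
#' variation down the rows), `CV` carries vertical-edge content (variation
#' across the columns), and `CD` carries diagonal detail. On the 2x2 block
#' `[[a, b], [c, d]]` (rows x cols) the coefficients are
#' `CA = (a+b+c+d)/2`, `CH = (a+b-c-d)/2`, `CV = (a-b+c-d)/2`,
#' `CD = (a-b-c+d)/2`.
#'
#' Odd-sized inputs are extended by periodization (the first row/column is
#' wrapped onto the end) so every subband has shape `ceiling(n/2)`; energy
#' conservation is only guaranteed for even sizes.
#'
#' @param image A numeric matrix with both dimensions >= 2.
#' @return An object of class `haar_subbands`: a list with numeric matrices
#'   `CA`, `CH`, `CV`, `CD`, all sharing one shape.
#' @examples
#' sb <- haar_dwt2(matrix(1:4, 2, 2, byrow = TRUE))
#' sb$CA  # 5
#' @seealso [haar_idwt2()], [decompose_volume()]
#' @export
haar_dwt2 <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  h <- nrow(image)
  w <- ncol(image)
  if (h < 2 || w < 2) {
    stop("`image` must be at least 2x2; got ", h, "x", w, call. = FALSE)
  }
  # periodization for odd sizes keeps subbands at ceiling(n/2)
  if (h %% 2L == 1L) image <- rbind(image, image[1L, , drop = FALSE])
  if (w %% 2L == 1L) image <- cbind(image, image[, 1L, drop = FALSE])
  ri <- seq(1L, nrow(image), by = 2L)
  ci <- seq(1L, ncol(image), by = 2L)
  a <- image[ri, ci, drop = FALSE]
  b <- image[ri, ci + 1L, drop = FALSE]
  cc <- image[ri + 1L, ci, drop = FALSE]
  d <- image[ri + 1L, ci + 1L, drop = FALSE]
  structure(
    list(
      CA = (a + b + cc + d) / 2,
      CH = (a + b - cc - d) / 2,
      CV = (a - b + cc - d) / 2,
      CD = (a - b - cc + d) / 2
    ),
    class = "haar_subbands",
    original_dim = c(h, w)
  )
}

#' Inverse single-level 2D Haar transform
#'
#' Reconstructs the image from its four Haar subbands. For subbands produced
#' by [haar_dwt2()] on an even-sized image the reconstruction is exact to
#' machine precision; for odd-sized originals the periodization pad is
#' dropped.
#'
#' @param subbands A `haar_subbands` object, or a list with numeric matrices
#'   `CA`, `CH`, `CV`, `CD` of identical shape.
#' @return A numeric matrix of twice the subband size in each dimension
#'   (minus the periodization pad when the original size was odd).
#' @export
haar_idwt2 <- function(subbands) {
  need <- c("CA", "CH", "CV", "CD")
  if (!all(need %in% names(subbands))) {
    stop("`subbands` must contain CA, CH, CV and CD", call. = FALSE)
  }
  sb <- lapply(subbands[need], function(m) {
    if (!is.matrix(m)) m <- as.matrix(m)
    m
  })
  dims <- vapply(sb, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("subband shapes differ: ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "),
         call. = FALSE)
  }
  a <- (sb$CA + sb$CH + sb$CV + sb$CD) / 2
  b <- (sb$CA + sb$CH - sb$CV - sb$CD) / 2
  cc <- (sb$CA - sb$CH + sb$CV - sb$CD) / 2
  d <- (sb$CA - sb$CH - sb$CV + sb$CD) / 2
  h2 <- nrow(a)
  w2 <- ncol(a)
  out <- matrix(0, 2L * h2, 2L * w2)
  ri <- seq(1L, 2L * h2, by = 2L)
  ci <- seq(1L, 2L * w2, by = 2L)
  out[ri, ci] <- a
  out[ri, ci + 1L] <- b
  out[ri + 1L, ci] <- cc
  out[ri + 1L, ci + 1L] <- d
  odim <- attr(subbands, "original_dim")
  if (!is.null(odim)) out <- out[seq_len(odim[1]), seq_len(odim[2]), drop = FALSE]
  out
}

#' @export
print.haar_subbands <- function(x, ...) {
  cat("<haar_subbands> one-level db1 decomposition,",
      paste(dim(x$CA), collapse = "x"), "per subband\n")
  invisible(x)
}

#' Slice-wise wavelet decomposition of a subject volume
#'
#' Applies [haar_dwt2()] to every slice of a `(n_slices, H, W)` volume
#' independently (no mixing across slices), yielding one half-resolution
#' coefficient stack per subband: the full-size `88 x 256 x 256` volume
#' becomes four `88 x 128 x 128` stacks.
#'
#' @param volume A [subject_volume()] or a numeric 3D array with the slice
#'   axis first.
#' @return An object of class `subband_volumes`: a list of 3D arrays `CA`,
#'   `CH`, `CV`, `CD`, each `(n_slices, ceiling(H/2), ceiling(W/2))`, with the
#'   subject id and label carried over when present.
#' @export
decompose_volume <- function(volume) {
  data <- if (inherits(volume, "subject_volume")) volume$data else volume
  if (!(is.array(data) && length(dim(data)) == 3L)) {
    stop("`volume` must be a 3D array or subject_volume", call. = FALSE)
  }
  n <- dim(data)[1]
  first <- haar_dwt2(data[1, , ])
  h2 <- nrow(first$CA)
  w2 <- ncol(first$CA)
  out <- lapply(c(CA = "CA", CH = "CH", CV = "CV", CD = "CD"),
                function(nm) array(0, dim = c(n, h2, w2)))
  for (j in seq_len(n)) {
    sb <- if (j == 1L) first else haar_dwt2(data[j, , ])
    out$CA[j, , ] <- sb$CA
    out$CH[j, , ] <- sb$CH
    out$CV[j, , ] <- sb$CV
    out$CD[j, , ] <- sb$CD
  }
  structure(
    out,
    class = "subband_volumes",
    subject_id = if (inherits(volume, "subject_volume")) volume$subject_id,
    label = if (inherits(volume, "subject_volume")) volume$label,
    original_dim = dim(data)
  )
}

#' @export
print.subband_volumes <- function(x, ...) {
  cat("<subband_volumes>", paste(dim(x$CA), collapse = "x"),
      "per subband (CA/CH/CV/CD)\n")
  id <- attr(x, "subject_id")
  if (!is.null(id)) cat("  subject:", id, "\n")
  invisible(x)
}

#' Nyquist radius of an image in cycles per image
#'
#' The largest radial spatial frequency representable on the image's discrete
#' frequency grid, `sqrt((H/2)^2 + (W/2)^2)`. An ideal lowpass at this radius
#' passes every frequency component.
#'
#' @param image A numeric matrix.
#' @return A single number, in cycles per image.
#' @export
nyquist_radius <- function(image) {
  sqrt((nrow(image) / 2)^2 + (ncol(image) / 2)^2)
}

#' Ideal radial frequency filter
#'
#' Applies an ideal (hard-mask) radial filter in the 2D discrete frequency
#' domain. Frequencies are measured as radius `sqrt(fx^2 + fy^2)` in cycles
#' per image. `lowpass` keeps radii `<= cutoff`; `highpass` keeps radii
#' `> cutoff`, so it always removes the DC component and maps a constant
#' image to zero. Used for ablating low- against high-frequency content of a
#' slice before classification.
#'
#' @param image A numeric matrix.
#' @param cutoff Radial cutoff in cycles per image; must be positive and at
#'   most [nyquist_radius()] of the image.
#' @param mode Either `"lowpass"` or `"highpass"`.
#' @return A real-valued matrix of the same shape.
#' @export
frequency_filter <- function(image, cutoff, mode = c("lowpass", "highpass")) {
  mode <- match.arg(mode)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  nr <- nyquist_radius(image)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > nr) {
    stop("`cutoff` must be in (0, ", format(nr), "] cycles per image",
         call. = FALSE)
  }
  h <- nrow(image)
  w <- ncol(image)
  # integer frequency indices, wrapped to +/- n/2, in cycles per image
  ky <- 0:(h - 1L)
  kx <- 0:(w - 1L)
  fy <- ifelse(ky <= h / 2, ky, ky - h)
  fx <- ifelse(kx <= w / 2, kx, kx - w)
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  mask <- if (mode == "lowpass") rad <= cutoff else rad > cutoff
  spec <- stats::fft(image) * mask
  Re(stats::fft(spec, inverse = TRUE)) / (h * w)
}
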