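#' Subject volume container
#'
#' A light container for one subject's slice stack: a `(n_slices, H, W)`
#' numeric array with the slice axis first (the sagittal axis; the first
#' stored NIfTI axis is used as-is, with no reorientation from the affine),
#' plus the subject id, binary label (or `NA` when unknown) and the original
#' stored shape.
#'
#' @param data A numeric 3D array `(n_slices, H, W)` of finite values.
#' @param subject_id Character subject identifier.
#' @param label 0, 1 or `NA`.
#' @param source_shape Original stored shape (defaults to `dim(data)`).
#' @return An object of class `subject_volume`.
#' @export
subject_volume <- function(data, subject_id = NA_character_, label = NA,
                           source_shape = dim(data)) {
  if (!(is.array(data) && length(dim(data)) == 3L && is.numeric(data))) {
    stop("`data` must be a numeric 3D array", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume contains ", sum(!is.finite(data)), " non-finite voxels",
         call. = FALSE)
  }
  if (!is.na(label) && !label %in% c(0, 1)) {
    stop("`label` must be 0, 1 or NA", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, data = data,
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         source_shape = as.integer(source_shape)),
    class = "subject_volume"
  )
}

#' @export
print.subject_volume <- function(x, ...) {
  cat("<subject_volume> ", paste(dim(x$data), collapse = "x"),
      if (!is.na(x$subject_id)) paste0("  id: ", x$subject_id),
      if (!is.na(x$label)) paste0("  label: ", x$label), "\n")
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a plain numeric array with the slice
#' axis first (slice, row, col — the stored axis order; no reorientation) and
#' floating-point storage. Errors on missing files, non-3D images, and
#' volumes containing NaN voxels.
#'
#' @param path Path to a NIfTI file.
#' @return A numeric 3D array with attribute `source_shape`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D image, got ", length(dim(arr)), "D (",
         paste(dim(arr), collapse = "x"), "): ", path, call. = FALSE)
  }
  n_bad <- sum(is.nan(arr))
  if (n_bad > 0) {
    stop("volume contains ", n_bad, " NaN voxels: ", path, call. = FALSE)
  }
  storage.mode(arr) <- "double"
  attr(arr, "source_shape") <- dim(arr)
  arr
}

#' Select the retained slice window
#'
#' Keeps `n_keep` contiguous slices from the stack. A number of initial and
#' final slices carry little anatomy, so by default an equal count is dropped
#' from each end: the window starts at `floor((N - n_keep) / 2)` (0-based),
#' e.g. slices 53..140 of a 192-slice stack for `n_keep = 88`. The start is
#' overridable. Selection preserves slice order and is idempotent: selecting
#' `n_keep` from an `n_keep`-slice stack is the identity.
#'
#' @param raw A numeric 3D array (slice axis first) or [subject_volume()].
#' @param n_keep Number of slices to retain (default 88).
#' @param window_start Optional 0-based index of the first retained slice;
#'   default centers the window.
#' @param subject_id,label Passed through to the returned [subject_volume()].
#' @return A [subject_volume()] with exactly `n_keep` slices.
#' @export
select_slices <- function(raw, n_keep = 88L, window_start = NULL,
                          subject_id = NA_character_, label = NA) {
  if (inherits(raw, "subject_volume")) {
    if (is.na(subject_id)) subject_id <- raw$subject_id
    if (is.na(label)) label <- raw$label
    src <- raw$source_shape
    raw <- raw$data
  } else {
    src <- attr(raw, "source_shape") %||% dim(raw)
  }
  n_keep <- as.integer(n_keep)
  n <- dim(raw)[1]
  if (n < n_keep) {
    stop("volume has ", n, " slices; cannot retain ", n_keep, call. = FALSE)
  }
  start <- if (is.null(window_start)) (n - n_keep) %/% 2L else
    as.integer(window_start)
  if (start < 0L || start + n_keep > n) {
    stop("window [", start, ", ", start + n_keep, ") outside 0..", n,
         call. = FALSE)
  }
  subject_volume(raw[start + seq_len(n_keep), , , drop = FALSE],
                 subject_id = subject_id, label = label, source_shape = src)
}

#' Min-max normalize a subject volume
#'
#' Affine rescaling of the whole volume to `[0, 1]`; a constant volume maps
#' to all zeros. Normalization is per volume, not per slice, so the relative
#' contrast between slices — which the energy feature encodes — is preserved.
#' Idempotent, and invariant to positive affine rescaling of the input.
#'
#' @param volume A [subject_volume()] or numeric 3D array.
#' @return The same type as the input, with values in `[0, 1]`.
#' @export
normalize_volume <- function(volume) {
  is_sv <- inherits(volume, "subject_volume")
  data <- if (is_sv) volume$data else volume
  rng <- range(data)
  data <- if (rng[2] > rng[1]) (data - rng[1]) / (rng[2] - rng[1]) else
    array(0, dim = dim(data))
  if (is_sv) {
    volume$data <- data
    volume
  } else {
    data
  }
}

#' Load, window and normalize one subject
#'
#' Convenience composition of [read_volume()], [select_slices()] and
#' [normalize_volume()] for one manifest row.
#'
#' @inheritParams read_volume
#' @inheritParams select_slices
#' @return A normalized [subject_volume()].
#' @export
load_subject <- function(path, subject_id = NA_character_, label = NA,
                         n_keep = 88L, window_start = NULL) {
  raw <- read_volume(path)
  sv <- select_slices(raw, n_keep = n_keep, window_start = window_start,
                      subject_id = subject_id, label = label)
  normalize_volume(sv)
}

#' Read a cohort manifest
#'
#' Reads a manifest CSV with header `subject_id,path,label,dataset`, checks
#' uniqueness of subject ids, binary labels, and that every referenced file
#' exists. Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with columns `subject_id`, `path`, `label`, `dataset`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "path", "label", "dataset")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- dplyr::select(m, dplyr::all_of(need))
  if (anyDuplicated(m$subject_id)) {
    stop("duplicate subject_ids in manifest", call. = FALSE)
  }
  if (!all(m$label %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  missing <- !file.exists(m$path)
  if (any(missing)) {
    stop("missing volume files: ",
         paste(utils::head(m$subject_id[missing], 5), collapse = ", "),
         call. = FALSE)
  }
  m$label <- as.integer(m$label)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
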