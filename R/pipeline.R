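#' Architecture dump for cross-framework verification
#'
#' Serializes the three architectures of a profile — layer lists, traced
#' output shapes and parameter counts — to a JSON-ready list (optionally
#' written to a file).
#'
#' @param profile `"paper"` or `"test"`.
#' @param path Optional output path for the JSON file.
#' @return The list, invisibly when `path` is given.
#' @export
architecture_dump <- function(profile = c("paper", "test"), path = NULL) {
  profile <- match.arg(profile)
  out <- purrr::map(
    c("conv1d_energy", "conv2d_fused", "conv3d_volume"),
    function(nm) {
      spec <- model_spec(nm, profile)
      pc <- parameter_count(spec)
      list(
        name = nm, profile = profile, input_shape = spec$input_shape,
        layers = purrr::map2(spec$layers, shape_trace(spec), function(l, s) {
          list(kind = l$kind, kernel = l$kernel, filters = l$filters,
               units = l$units, activation = l$activation, rate = l$rate,
               output_shape = s)
        }),
        total_parameters = pc$total, trainable = pc$trainable,
        non_trainable = pc$non_trainable
      )
    }
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(out))
  }
  out
}

#' Split a manifest into stratified train and test parts
#'
#' @param manifest A manifest tibble.
#' @param test_fraction Fraction of each class held out for testing.
#' @param seed Integer seed for the stratified draw.
#' @return A list with tibbles `train` and `test`.
#' @export
split_manifest <- function(manifest, test_fraction = 0.2, seed = 1L) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  test_idx <- unlist(lapply(unique(manifest$label), function(cl) {
    cls <- which(manifest$label == cl)
    sample(cls, max(1L, round(length(cls) * test_fraction)))
  }))
  list(train = manifest[-test_idx, ], test = manifest[test_idx, ])
}

#' Run the full pipeline end to end
#'
#' Orchestrates simulate (optional) -> load -> wavelet decompose -> extract
#' route features -> train the three routes -> majority-vote ensemble ->
#' report. With `simulate` set, a phantom cohort is generated and split
#' stratified into train/test; alternatively explicit train and test
#' manifests run the cross-cohort protocol. Reports (metrics JSON + CSV,
#' per-route confusion matrices, architecture dump, training histories, and
#' the resolved configuration with every seed) are written under `out_dir`.
#' Deterministic: identical configuration and seed reproduce identical
#' reports.
#'
#' @param out_dir Output directory for reports (created if needed).
#' @param simulate Optional list of [phantom_config()] arguments plus
#'   `n_per_class`; mutually exclusive with the manifests.
#' @param train_manifest,test_manifest Manifest tibbles (or paths) for the
#'   cross-cohort protocol.
#' @param cfg A [train_config()].
#' @param profile Architecture profile (`"test"` scales the networks to the
#'   phantom test shapes; `"paper"` uses the full-size reference shapes).
#' @param n_keep Retained slices per subject; defaults to the simulated
#'   cohort's `n_slices` or 88.
#' @param test_fraction Held-out fraction when splitting a simulated cohort.
#' @param binding Route-to-subband binding.
#' @param seed Master seed; simulation, split and training seeds derive
#'   from it.
#' @return An `mvmdm_generalization` result (metrics, confusion matrices,
#'   predictions, models), invisibly; reports on disk under `out_dir`.
#' @export
run_pipeline <- function(out_dir, simulate = NULL, train_manifest = NULL,
                         test_manifest = NULL, cfg = train_config(),
                         profile = c("test", "paper"), n_keep = NULL,
                         test_fraction = 0.2,
                         binding = c(d1 = "CD", d2 = "CH", d3 = "CV"),
                         seed = cfg$seed) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(simulate)) {
    n_per_class <- simulate$n_per_class %||% 20L
    pc_args <- simulate[setdiff(names(simulate), "n_per_class")]
    pcfg <- do.call(phantom_config, pc_args)
    message("simulate: ", 2 * n_per_class, " subjects (",
            pcfg$n_slices, "x", pcfg$slice_size, "x", pcfg$slice_size, ")")
    manifest <- generate_cohort(n_per_class, pcfg,
                                dir = file.path(out_dir, "cohort"),
                                seed = seed)
    parts <- split_manifest(manifest, test_fraction, seed = seed)
    train_manifest <- parts$train
    test_manifest <- parts$test
    n_keep <- n_keep %||% pcfg$n_slices
  } else {
    if (is.character(train_manifest)) {
      train_manifest <- read_manifest(train_manifest)
    }
    if (is.character(test_manifest)) {
      test_manifest <- read_manifest(test_manifest)
    }
    if (is.null(train_manifest) || is.null(test_manifest)) {
      stop("supply either `simulate` or both manifests", call. = FALSE)
    }
    n_keep <- n_keep %||% 88L
  }

  cfg$seed <- as.integer(seed)
  message("train: ", nrow(train_manifest), " subjects / test: ",
          nrow(test_manifest), " subjects, profile ", profile)
  res <- generalization_run(train_manifest, test_manifest, cfg = cfg,
                            n_keep = n_keep, profile = profile,
                            binding = binding)

  readr::write_csv(res$metrics, file.path(out_dir, "metrics.csv"))
  jsonlite::write_json(
    list(seed = seed, profile = profile, n_keep = n_keep,
         binding = as.list(binding),
         config = unclass(cfg),
         metrics = res$metrics,
         confusion = purrr::map(res$confusion, unclass)),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cmrows <- purrr::imap_dfr(res$confusion, function(cm, nm) {
    tibble::tibble(model = nm, TN = cm$TN, FP = cm$FP, FN = cm$FN,
                   TP = cm$TP)
  })
  readr::write_csv(cmrows, file.path(out_dir, "confusion_matrices.csv"))
  hist <- purrr::imap_dfr(res$models, function(m, route) {
    dplyr::mutate(m$history, route = route, .before = 1)
  })
  readr::write_csv(hist, file.path(out_dir, "training_history.csv"))
  architecture_dump(profile, file.path(out_dir, "architecture.json"))

  invisible(res)
}
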