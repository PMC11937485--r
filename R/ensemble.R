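#' Majority vote over route predictions
#'
#' Fuses the binary votes of the route classifiers by majority. With the
#' three routes (1D, 2D, 3D) a tie is impossible; to keep the operation
#' total for even ensembles, a tie falls back to thresholding the mean of
#' the supplied probabilities (an extension; error if probabilities are
#' absent on a tie). The vote is invariant to vote order.
#'
#' @param votes Binary vector of votes (length 3 for the standard ensemble).
#' @param probabilities Optional numeric vector of the routes' sigmoid
#'   probabilities, used only to break ties in even ensembles.
#' @param threshold Threshold for the tie-break on mean probability.
#' @return 0 or 1.
#' @export
max_vote <- function(votes, probabilities = NULL, threshold = 0.5) {
  if (!length(votes)) stop("no votes supplied", call. = FALSE)
  if (!all(votes %in% c(0, 1))) {
    stop("votes must be binary 0/1", call. = FALSE)
  }
  ones <- sum(votes == 1)
  zeros <- length(votes) - ones
  if (ones != zeros) return(as.integer(ones > zeros))
  if (is.null(probabilities)) {
    stop("tied vote and no probabilities for the tie-break", call. = FALSE)
  }
  as.integer(mean(probabilities) >= threshold)
}

#' Confusion matrix for binary predictions
#'
#' Counts TP/TN/FP/FN with class 1 (disease) as the positive class.
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return An object of class `mvmdm_confusion`: a list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` lengths differ", call. = FALSE)
  }
  if (!length(y_true)) stop("empty vectors", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("entries must be binary 0/1", call. = FALSE)
  }
  structure(
    list(TP = sum(y_true == 1 & y_pred == 1),
         TN = sum(y_true == 0 & y_pred == 0),
         FP = sum(y_true == 0 & y_pred == 1),
         FN = sum(y_true == 1 & y_pred == 0)),
    class = "mvmdm_confusion"
  )
}

#' @export
print.mvmdm_confusion <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(true = c("healthy", "disease"),
                              predicted = c("healthy", "disease")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the five standard metrics as percentages (full precision; round
#' for display): accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and F1 as the harmonic mean of
#' precision and sensitivity. A metric whose denominator is zero is
#' undefined and reported as `NA`, never as 0.
#'
#' @param cm An [confusion_matrix()] result, or a list/vector with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return A one-row tibble with columns `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`, all in percent.
#' @export
compute_metrics <- function(cm) {
  cm <- as.list(cm)
  need <- c("TP", "TN", "FP", "FN")
  stopifnot(all(need %in% names(cm)))
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  n <- tp + tn + fp + fn
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- safe(tp, tp + fp)
  sensitivity <- safe(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  tibble::tibble(
    accuracy = 100 * (tp + tn) / n,
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe(tn, tn + fp),
    f1 = f1
  )
}

#' Extract the three route feature sets for a cohort
#'
#' Loads, windows, normalizes and wavelet-decomposes every subject of a
#' manifest, then assembles the three route feature matrices: per-slice
#' energies of the 1D-route subband, mean-fused images of the 2D-route
#' subband, and the full 3D-route subband stacks.
#'
#' @inheritParams cohort_energy_features
#' @param binding Route-to-subband binding as in [subject_features()].
#' @return A list with feature matrices `d1`, `d2`, `d3` (each carrying an
#'   `input_shape` attribute), labels `y` and `subject_id`.
#' @export
cohort_route_features <- function(manifest, n_keep = 88L,
                                  binding = c(d1 = "CD", d2 = "CH",
                                              d3 = "CV"),
                                  method = c("central", "sobel")) {
  method <- match.arg(method)
  feats <- purrr::pmap(
    list(manifest$subject_id, manifest$path, manifest$label),
    function(id, path, label) {
      vol <- load_subject(path, subject_id = id, label = label,
                          n_keep = n_keep)
      subject_features(decompose_volume(vol), binding = binding,
                       method = method)
    }
  )
  list(
    d1 = features_to_matrix(purrr::map(feats, "energy")),
    d2 = features_to_matrix(purrr::map(feats, "fused")),
    d3 = features_to_matrix(purrr::map(feats, "volume")),
    y = as.integer(manifest$label),
    subject_id = manifest$subject_id
  )
}

route_specs <- function(profile, features) {
  list(
    d1 = model_spec("conv1d_energy", profile,
                    input_shape = attr(features$d1, "input_shape")),
    d2 = model_spec("conv2d_fused", profile,
                    input_shape = attr(features$d2, "input_shape")),
    d3 = model_spec("conv3d_volume", profile,
                    input_shape = attr(features$d3, "input_shape"))
  )
}

#' Train the three routes on one cohort's features
#'
#' @param features Route features from [cohort_route_features()].
#' @param cfg A [train_config()]; each route trains with a seed derived
#'   deterministically from `cfg$seed`.
#' @param profile Architecture profile passed to [model_spec()].
#' @return Named list of three `mvmdm_model`s (`d1`, `d2`, `d3`).
#' @export
train_routes <- function(features, cfg = train_config(),
                         profile = c("test", "paper")) {
  profile <- match.arg(profile)
  specs <- route_specs(profile, features)
  purrr::imap(specs, function(spec, route) {
    rcfg <- cfg
    rcfg$seed <- subject_seed(cfg$seed, match(route, names(specs)))
    train_model(spec, features[[route]], features$y, cfg = rcfg)
  })
}

#' Predict a cohort with the three routes and their majority vote
#'
#' @param models Route models from [train_routes()].
#' @param features Route features from [cohort_route_features()].
#' @param threshold Decision threshold (default: each model's).
#' @return A tibble with per-route probabilities and votes, the ensemble
#'   prediction `mvmdm`, and the true `label`.
#' @export
predict_routes <- function(models, features, threshold = NULL) {
  preds <- purrr::imap(models, function(m, route) {
    classify(m, features[[route]], threshold = threshold)
  })
  votes <- cbind(preds$d1$label, preds$d2$label, preds$d3$label)
  probs <- cbind(preds$d1$probability, preds$d2$probability,
                 preds$d3$probability)
  mv <- vapply(seq_len(nrow(votes)), function(i) {
    max_vote(votes[i, ], probs[i, ])
  }, integer(1))
  tibble::tibble(
    subject_id = features$subject_id,
    label = features$y,
    p_1d = preds$d1$probability, vote_1d = preds$d1$label,
    p_2d = preds$d2$probability, vote_2d = preds$d2$label,
    p_3d = preds$d3$probability, vote_3d = preds$d3$label,
    mvmdm = mv
  )
}

route_metrics_table <- function(pred) {
  routes <- c(`1D-CNN` = "vote_1d", `2D-CNN` = "vote_2d",
              `3D-CNN` = "vote_3d", MVMDM = "mvmdm")
  cms <- purrr::map(routes, function(col) {
    confusion_matrix(pred$label, pred[[col]])
  })
  metrics <- purrr::imap_dfr(cms, function(cm, nm) {
    dplyr::bind_cols(tibble::tibble(model = nm), compute_metrics(cm))
  })
  list(metrics = metrics, confusion = cms)
}

#' Cross-cohort generalization run
#'
#' Trains all three routes on one cohort and evaluates them — individually
#' and under the majority-vote ensemble — on a disjoint cohort, the
#' train-on-one-dataset / test-on-another protocol. Subject leakage between
#' the manifests is a hard error.
#'
#' @param train_manifest,test_manifest Manifest tibbles with disjoint
#'   subject ids.
#' @param cfg A [train_config()].
#' @param n_keep Retained slices per subject.
#' @param profile Architecture profile.
#' @param binding Route-to-subband binding.
#' @return A list of class `mvmdm_generalization`: `metrics` (tibble, one
#'   row per route plus MVMDM), `confusion` (named list of confusion
#'   matrices), `predictions` (per-subject tibble), and the fitted `models`.
#' @export
generalization_run <- function(train_manifest, test_manifest,
                               cfg = train_config(), n_keep = 88L,
                               profile = c("test", "paper"),
                               binding = c(d1 = "CD", d2 = "CH",
                                           d3 = "CV")) {
  profile <- match.arg(profile)
  leaked <- intersect(train_manifest$subject_id, test_manifest$subject_id)
  if (length(leaked)) {
    stop("subject leakage between train and test manifests: ",
         paste(utils::head(leaked, 5), collapse = ", "), call. = FALSE)
  }
  ftr <- cohort_route_features(train_manifest, n_keep = n_keep,
                               binding = binding)
  fte <- cohort_route_features(test_manifest, n_keep = n_keep,
                               binding = binding)
  models <- train_routes(ftr, cfg = cfg, profile = profile)
  pred <- predict_routes(models, fte)
  out <- route_metrics_table(pred)
  structure(
    list(metrics = out$metrics, confusion = out$confusion,
         predictions = pred, models = models),
    class = "mvmdm_generalization"
  )
}

#' @export
print.mvmdm_generalization <- function(x, ...) {
  cat("<mvmdm_generalization>", nrow(x$predictions), "test subjects\n")
  print(x$metrics)
  invisible(x)
}
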