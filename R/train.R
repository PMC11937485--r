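#' Assemble a feature matrix for one route
#'
#' Stacks per-subject route features into the flat sample-by-feature matrix
#' the training engine consumes (column-major array layout, channels last).
#'
#' @param features A list of per-subject features: numeric vectors (1D
#'   route), matrices (2D route) or 3D arrays (3D route), all of identical
#'   shape.
#' @return A numeric matrix with one row per subject and attribute
#'   `input_shape`.
#' @export
features_to_matrix <- function(features) {
  stopifnot(length(features) >= 1)
  shp <- dim(features[[1]]) %||% length(features[[1]])
  x <- t(vapply(features, function(f) {
    fd <- dim(f) %||% length(f)
    if (!identical(fd, shp)) {
      stop("inconsistent feature shapes: ", paste(shp, collapse = "x"),
           " vs ", paste(fd, collapse = "x"), call. = FALSE)
    }
    as.vector(f)
  }, numeric(prod(shp))))
  attr(x, "input_shape") <- as.integer(c(shp, 1L))
  x
}

check_input_shape <- function(spec, x) {
  want <- prod(spec$input_shape)
  if (ncol(x) != want) {
    stop("feature width ", ncol(x), " does not match spec input (",
         paste(spec$input_shape, collapse = ", "), ") = ", want, " values",
         call. = FALSE)
  }
}

#' Train one route's network
#'
#' Trains the network described by `spec` on a sample-by-feature matrix with
#' binary labels, minimizing binary cross-entropy with Adam. All stochastic
#' sources (weight initialization, epoch shuffling, dropout, the optional
#' validation split) are driven by `cfg$seed`, so a repeated call returns an
#' identical model and history. With `validation_split > 0` the returned
#' parameters are the best-epoch checkpoint by validation accuracy (ties
#' broken by lower validation loss); otherwise the final epoch's.
#' `epochs = 0` returns the untouched initialization with an empty history.
#'
#' @param spec An [model_spec()].
#' @param x Feature matrix (one row per subject), e.g. from
#'   [features_to_matrix()].
#' @param y Binary labels (0/1), length `nrow(x)`.
#' @param cfg A [train_config()].
#' @param standardize Standardize features using training-set statistics:
#'   per-feature for the 1D route, a single global mean/sd for image and
#'   volume routes (preserves spatial structure). Stored in the model and
#'   re-applied at prediction.
#' @param restarts Maximum number of additional deterministic restarts (with
#'   seeds derived from `cfg$seed`) attempted when a fit collapses — small
#'   ReLU networks occasionally die into a constant-output state from an
#'   unlucky initialization. The first attempt whose accuracy criterion
#'   (validation accuracy when a split is configured, else final training
#'   accuracy) reaches `restart_threshold` is kept; otherwise the best
#'   attempt.
#' @param restart_threshold Accuracy criterion above which a fit is accepted
#'   without further restarts.
#' @return An object of class `mvmdm_model`: the fitted network, the spec,
#'   the config, standardization constants, and a per-epoch `history` tibble
#'   (`epoch`, `loss`, `accuracy`, and validation columns when split > 0).
#' @export
train_model <- function(spec, x, y, cfg = train_config(),
                        standardize = TRUE, restarts = 2L,
                        restart_threshold = 0.7) {
  stopifnot(inherits(spec, "mvmdm_model_spec"),
            inherits(cfg, "mvmdm_train_config"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  if (length(unique(y)) < 2 && cfg$epochs > 0) {
    stop("training set contains a single class", call. = FALSE)
  }
  check_input_shape(spec, x)

  std <- NULL
  if (standardize) {
    if (spec$name == "conv1d_energy") {
      ctr <- colMeans(x)
      scl <- pmax(apply(x, 2, stats::sd), 1e-8)
    } else {
      ctr <- rep(mean(x), ncol(x))
      scl <- rep(max(stats::sd(x), 1e-8), ncol(x))
    }
    std <- list(center = ctr, scale = scl)
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  }

  attempt_seeds <- c(cfg$seed,
                     vapply(seq_len(max(restarts, 0L)),
                            function(a) subject_seed(cfg$seed, 7000L + a),
                            integer(1)))
  best_fit <- NULL
  for (attempt_seed in attempt_seeds) {
    fit <- train_once(spec, x, y, cfg, attempt_seed)
    if (is.null(best_fit) || fit$criterion > best_fit$criterion) {
      best_fit <- fit
    }
    if (cfg$epochs == 0L || best_fit$criterion >= restart_threshold) break
  }
  net <- best_fit$net

  structure(
    list(network = net, spec = spec, config = cfg, standardize = std,
         history = best_fit$history),
    class = "mvmdm_model"
  )
}

# one seeded training run; returns the fitted network, its history and the
# accuracy criterion used to detect failed (collapsed) fits
train_once <- function(spec, x, y, cfg, seed) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  net <- build_network(spec)

  # optional stratified validation split for checkpointing
  val_idx <- integer(0)
  if (cfg$validation_split > 0) {
    val_idx <- unlist(lapply(unique(y), function(cl) {
      cls <- which(y == cl)
      sample(cls, max(1L, round(length(cls) * cfg$validation_split)))
    }))
    x_val <- x[val_idx, , drop = FALSE]
    y_val <- y[val_idx]
    x <- x[-val_idx, , drop = FALSE]
    y <- y[-val_idx]
  }

  n <- nrow(x)
  state <- adam_init(net)
  t_step <- 0L
  history <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, loss = Inf, layers = net$layers)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    ep_correct <- 0
    for (s in starts) {
      bi <- ord[s:min(s + cfg$batch_size - 1L, n)]
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi]
      fw <- network_forward(net, xb, training = TRUE)
      net <- fw$net  # batchnorm running stats
      logits <- fw$logits
      loss <- bce_loss(logits, yb)
      if (!is.finite(loss)) {
        stop("NaN/Inf loss at epoch ", epoch, " (batch starting ", s,
             "); try a lower learning rate", call. = FALSE)
      }
      p <- stats::plogis(logits)
      ep_loss <- ep_loss + loss * length(bi)
      ep_correct <- ep_correct + sum((p >= cfg$threshold) == (yb == 1))
      dlogit <- matrix((p - yb) / length(bi), ncol = 1)
      grads <- network_backward(net, fw$caches, dlogit, length(bi))
      t_step <- t_step + 1L
      upd <- adam_step(net, grads, state, cfg$learning_rate, t_step)
      net <- upd$net
      state <- upd$state
    }
    row <- tibble::tibble(epoch = epoch, loss = ep_loss / n,
                          accuracy = ep_correct / n)
    if (length(val_idx)) {
      vlog <- network_forward(net, x_val, training = FALSE)$logits
      row$val_loss <- bce_loss(vlog, y_val)
      row$val_accuracy <-
        mean((stats::plogis(vlog) >= cfg$threshold) == (y_val == 1))
      if (row$val_accuracy > best$acc ||
          (row$val_accuracy == best$acc && row$val_loss < best$loss)) {
        best <- list(acc = row$val_accuracy, loss = row$val_loss,
                     layers = net$layers)
      }
    }
    history[[epoch]] <- row
  }
  if (length(val_idx) && best$acc > -Inf) net$layers <- best$layers

  history <- dplyr::bind_rows(history)
  criterion <- if (cfg$epochs == 0L) {
    Inf
  } else if (length(val_idx)) {
    max(best$acc, 0)
  } else {
    utils::tail(history$accuracy, 1)
  }
  list(net = net, history = history, criterion = criterion)
}

#' @export
print.mvmdm_model <- function(x, ...) {
  cat("<mvmdm_model> ", x$spec$name, " [", x$spec$profile, "], ",
      nrow(x$history), " epochs trained\n", sep = "")
  if (nrow(x$history)) {
    last <- utils::tail(x$history, 1)
    cat(sprintf("  final loss %.4f, training accuracy %.3f\n",
                last$loss, last$accuracy))
  }
  invisible(x)
}

#' Classify samples with a trained route model
#'
#' Applies the fitted network and thresholds the sigmoid output: a sample is
#' assigned class 1 iff its probability is at least `threshold`.
#'
#' @param model An `mvmdm_model` from [train_model()].
#' @param x Feature matrix (one row per sample) in the model's input layout.
#' @param threshold Decision threshold, strictly inside (0, 1); defaults to
#'   the training config's.
#' @return A tibble with columns `probability` and `label`.
#' @export
classify <- function(model, x, threshold = NULL) {
  stopifnot(inherits(model, "mvmdm_model"))
  threshold <- threshold %||% model$config$threshold
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be strictly inside (0, 1)", call. = FALSE)
  }
  x <- as.matrix(x)
  check_input_shape(model$spec, x)
  if (!is.null(model$standardize)) {
    x <- sweep(sweep(x, 2, model$standardize$center), 2,
               model$standardize$scale, "/")
  }
  logits <- network_forward(model$network, x, training = FALSE)$logits
  p <- as.vector(stats::plogis(logits))
  tibble::tibble(probability = p, label = as.integer(p >= threshold))
}

#' @export
predict.mvmdm_model <- function(object, newdata, ...) {
  classify(object, newdata, ...)
}

#' Stratified k-fold evaluation across seeds
#'
#' Runs stratified k-fold cross-validation of one route for each seed in
#' `seeds`: fold assignment, initialization and shuffling are all derived
#' from the seed, so the full table is reproducible. Reports per-fold
#' held-out metrics plus the per-seed mean and standard deviation of
#' accuracy — the harness behind seed-stability claims.
#'
#' @param x Feature matrix (one row per subject).
#' @param y Binary labels.
#' @param spec An [model_spec()].
#' @param cfg A [train_config()]; its `k_folds` and training settings apply.
#' @param seeds Integer vector of seeds (non-empty).
#' @return A tibble with one row per (seed, fold): `seed`, `fold`,
#'   `accuracy`, `precision`, `sensitivity`, `specificity`, `f1` (fractions
#'   in \[0, 1\] for accuracy; metric columns as percentages per
#'   [compute_metrics()]), with attribute `by_seed` — a tibble of per-seed
#'   mean accuracy and SD.
#' @export
kfold_evaluate <- function(x, y, spec, cfg = train_config(), seeds = 1L) {
  if (!length(seeds)) stop("`seeds` must be non-empty", call. = FALSE)
  x <- as.matrix(x)
  y <- as.integer(y)
  k <- cfg$k_folds
  if (length(unique(y)) < 2) {
    stop("both classes must be present for stratified folds", call. = FALSE)
  }
  if (min(table(y)) < k) {
    stop("fewer subjects per class (", min(table(y)), ") than folds (", k,
         ")", call. = FALSE)
  }
  rows <- purrr::map_dfr(seeds, function(seed) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    fold <- integer(length(y))
    for (cl in unique(y)) {
      cls <- which(y == cl)
      fold[cls] <- sample(rep_len(seq_len(k), length(cls)))
    }
    purrr::map_dfr(seq_len(k), function(f) {
      tr <- fold != f
      fit <- train_model(spec, x[tr, , drop = FALSE], y[tr],
                         cfg = train_config(
                           learning_rate = cfg$learning_rate,
                           epochs = cfg$epochs, batch_size = cfg$batch_size,
                           k_folds = cfg$k_folds,
                           seed = subject_seed(seed, f),
                           threshold = cfg$threshold,
                           validation_split = cfg$validation_split
                         ))
      pred <- classify(fit, x[!tr, , drop = FALSE])
      cm <- confusion_matrix(y[!tr], pred$label)
      met <- compute_metrics(cm)
      tibble::tibble(seed = seed, fold = f,
                     accuracy = (cm$TP + cm$TN) / sum(unlist(cm[1:4])),
                     precision = met$precision,
                     sensitivity = met$sensitivity,
                     specificity = met$specificity, f1 = met$f1)
    })
  })
  by_seed <- dplyr::summarise(
    dplyr::group_by(rows, .data$seed),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = stats::sd(.data$accuracy),
    .groups = "drop"
  )
  attr(rows, "by_seed") <- by_seed
  class(rows) <- c("mvmdm_kfold", class(rows))
  rows
}
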