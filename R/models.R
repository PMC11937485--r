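layer_spec <- function(kind, kernel = NULL, filters = NULL, units = NULL,
                       activation = "none", rate = NULL) {
  if (!is.null(kernel) && any(kernel < 1)) {
    stop("kernel dimensions must be positive", call. = FALSE)
  }
  if (!is.null(rate) && (rate < 0 || rate >= 1)) {
    stop("dropout rate must be in [0, 1)", call. = FALSE)
  }
  list(kind = kind, kernel = kernel, filters = filters, units = units,
       activation = activation, rate = rate)
}

#' Declarative architecture specification for the three routes
#'
#' Returns the layer list of one of the three networks. The `"paper"` profile
#' carries the full-size reference architectures exactly:
#'
#' * `conv1d_energy` — input `(88, 1)` energy profile:
#'   conv(3, 32) / pool(2) / conv(3, 64) / pool(2) / flatten /
#'   dense(64) / dense(1, sigmoid); 88,385 parameters.
#' * `conv2d_fused` — input `(128, 128, 1)` fused image: three
#'   conv(3x3) + batchnorm + pool(2x2) blocks with 32/64/128 filters,
#'   flatten (25088), dense(128), dropout(0.2), dense(1, sigmoid);
#'   3,305,089 parameters (448 non-trainable).
#' * `conv3d_volume` — input `(88, 128, 128, 1)` subband volume: four
#'   conv(2x3x3) + pool(1x2x2) pairs with 32/64/64/64 filters, flatten
#'   (193536), dense(128), dense(1, sigmoid); 24,957,985 parameters.
#'
#' All convolutions are unpadded ("valid"), stride 1; hidden activations are
#' ReLU and the single output unit is sigmoid (a softmax over one logit is
#' degenerate, so the binary output is a sigmoid probability). The `"test"`
#' profile keeps the same topology at reduced width/depth for the scaled
#' phantom volumes (16 slices of 64x64, subbands 16x32x32).
#'
#' @param kind One of `"conv1d_energy"`, `"conv2d_fused"`, `"conv3d_volume"`.
#' @param profile `"paper"` (default) or `"test"`.
#' @param input_shape Optional override of the input shape (spatial dims then
#'   channels).
#' @return An object of class `mvmdm_model_spec` with fields `name`,
#'   `input_shape`, `layers`.
#' @export
model_spec <- function(kind = c("conv1d_energy", "conv2d_fused",
                                "conv3d_volume"),
                       profile = c("paper", "test"), input_shape = NULL) {
  kind <- match.arg(kind)
  profile <- match.arg(profile)
  paper <- profile == "paper"
  if (kind == "conv1d_energy") {
    n <- if (paper) 88L else 16L
    f <- if (paper) c(32L, 64L) else c(8L, 16L)
    du <- if (paper) 64L else 16L
    shape <- input_shape %||% c(n, 1L)
    layers <- list(
      layer_spec("conv1d", kernel = 3L, filters = f[1], activation = "relu"),
      layer_spec("maxpool1d", kernel = 2L),
      layer_spec("conv1d", kernel = 3L, filters = f[2], activation = "relu"),
      layer_spec("maxpool1d", kernel = 2L),
      layer_spec("flatten"),
      layer_spec("dense", units = du, activation = "relu"),
      layer_spec("dense", units = 1L, activation = "sigmoid")
    )
  } else if (kind == "conv2d_fused") {
    side <- if (paper) 128L else 32L
    f <- if (paper) c(32L, 64L, 128L) else c(8L, 16L, 32L)
    du <- if (paper) 128L else 32L
    shape <- input_shape %||% c(side, side, 1L)
    blocks <- purrr::map(f, function(nf) list(
      layer_spec("conv2d", kernel = c(3L, 3L), filters = nf,
                 activation = "relu"),
      layer_spec("batchnorm"),
      layer_spec("maxpool2d", kernel = c(2L, 2L))
    ))
    layers <- c(
      purrr::flatten(blocks),
      list(
        layer_spec("flatten"),
        layer_spec("dense", units = du, activation = "relu"),
        layer_spec("dropout", rate = 0.2),
        layer_spec("dense", units = 1L, activation = "sigmoid")
      )
    )
  } else {
    if (paper) {
      shape <- input_shape %||% c(88L, 128L, 128L, 1L)
      f <- c(32L, 64L, 64L, 64L)
      du <- 128L
    } else {
      shape <- input_shape %||% c(16L, 32L, 32L, 1L)
      f <- c(8L, 16L)
      du <- 32L
    }
    pairs <- purrr::map(f, function(nf) list(
      layer_spec("conv3d", kernel = c(2L, 3L, 3L), filters = nf,
                 activation = "relu"),
      layer_spec("maxpool3d", kernel = c(1L, 2L, 2L))
    ))
    layers <- c(
      purrr::flatten(pairs),
      list(
        layer_spec("flatten"),
        layer_spec("dense", units = du, activation = "relu"),
        layer_spec("dense", units = 1L, activation = "sigmoid")
      )
    )
  }
  spec <- structure(
    list(name = kind, profile = profile, input_shape = as.integer(shape),
         layers = layers),
    class = "mvmdm_model_spec"
  )
  # a spec must trace to a valid final dense(1, sigmoid)
  tr <- shape_trace(spec)
  stopifnot(utils::tail(tr, 1)[[1]] == 1L)
  spec
}

#' Symbolic shape trace of an architecture
#'
#' Propagates the input shape through the layer list with unpadded-stride-1
#' convolution arithmetic (`out = in - k + 1` per spatial axis), floor
#' pooling (`out = floor(in / p)`), and flattening (product of dims). Errors
#' if any intermediate dimension becomes non-positive.
#'
#' @param spec An [model_spec()] object.
#' @return A list of integer vectors, one output shape per layer (channels
#'   last; dense/flatten shapes are scalars).
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "mvmdm_model_spec"))
  shape <- spec$input_shape
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    shape <- switch(
      ly$kind,
      conv1d = , conv2d = , conv3d = {
        sp <- shape[-length(shape)] - ly$kernel + 1L
        if (any(sp < 1L)) {
          stop("layer ", i, " (", ly$kind, ") collapses shape to ",
               paste(sp, collapse = "x"), call. = FALSE)
        }
        c(sp, ly$filters)
      },
      maxpool1d = , maxpool2d = , maxpool3d = {
        nsp <- length(shape) - 1L
        sp <- shape[seq_len(nsp)] %/% ly$kernel
        if (any(sp < 1L)) {
          stop("layer ", i, " (", ly$kind, ") collapses shape", call. = FALSE)
        }
        c(sp, shape[length(shape)])
      },
      batchnorm = , dropout = shape,
      flatten = prod(shape),
      dense = {
        if (length(shape) != 1L) {
          stop("dense layer ", i, " needs a flat input", call. = FALSE)
        }
        ly$units
      },
      stop("unknown layer kind: ", ly$kind, call. = FALSE)
    )
    out[[i]] <- as.integer(shape)
  }
  out
}

#' Parameter count of an architecture
#'
#' Counts weights layer by layer: convolutions contribute
#' `prod(kernel) * c_in * c_out + c_out`, dense layers `n_in * n_out + n_out`,
#' batch normalization `4 * channels` (scale and shift trainable; running
#' mean and variance not), and pooling/flatten/dropout nothing.
#'
#' @param spec An [model_spec()] object.
#' @return A list with `total`, `trainable`, `non_trainable` and a per-layer
#'   tibble `by_layer`.
#' @export
parameter_count <- function(spec) {
  stopifnot(inherits(spec, "mvmdm_model_spec"))
  shapes <- c(list(spec$input_shape), shape_trace(spec))
  rows <- purrr::imap(spec$layers, function(ly, i) {
    ins <- shapes[[i]]
    outs <- shapes[[i + 1]]
    p <- switch(
      ly$kind,
      conv1d = , conv2d = , conv3d = {
        cin <- ins[length(ins)]
        cout <- ly$filters
        c(prod(ly$kernel) * cin * cout + cout, 0)
      },
      dense = c(ins * ly$units + ly$units, 0),
      batchnorm = {
        ch <- ins[length(ins)]
        c(2 * ch, 2 * ch)
      },
      c(0, 0)
    )
    tibble::tibble(layer = i, kind = ly$kind,
                   output_shape = paste(outs, collapse = "x"),
                   trainable = p[1], non_trainable = p[2])
  })
  by_layer <- dplyr::bind_rows(rows)
  list(
    total = sum(by_layer$trainable) + sum(by_layer$non_trainable),
    trainable = sum(by_layer$trainable),
    non_trainable = sum(by_layer$non_trainable),
    by_layer = by_layer
  )
}

#' @export
print.mvmdm_model_spec <- function(x, ...) {
  pc <- parameter_count(x)
  cat("<mvmdm_model_spec> ", x$name, " [", x$profile, "], input (",
      paste(x$input_shape, collapse = ", "), ")\n", sep = "")
  tr <- shape_trace(x)
  for (i in seq_along(x$layers)) {
    cat(sprintf("  %2d %-10s -> (%s)\n", i, x$layers[[i]]$kind,
                paste(tr[[i]], collapse = ", ")))
  }
  cat("  parameters:", format(pc$total, big.mark = ","),
      "(", format(pc$non_trainable, big.mark = ","), "non-trainable )\n")
  invisible(x)
}

#' Training configuration
#'
#' Hyper-parameters of the training harness. Defaults are the reference
#' settings: Adam, learning rate 0.001, 20 epochs, batch size 32, 5-fold
#' cross-validation, decision threshold 0.5.
#'
#' @param learning_rate Adam step size.
#' @param epochs Number of passes over the training set (>= 0).
#' @param batch_size Minibatch size.
#' @param k_folds Folds for [kfold_evaluate()] (>= 2).
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and fold assignment.
#' @param threshold Classification threshold on the sigmoid probability,
#'   in (0, 1).
#' @param validation_split Fraction of the training set held out for
#'   best-epoch checkpointing (by validation loss); 0 disables.
#' @return An object of class `mvmdm_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 20L,
                         batch_size = 32L, k_folds = 5L, seed = 1L,
                         threshold = 0.5, validation_split = 0) {
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  if (k_folds < 2) stop("`k_folds` must be >= 2", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be strictly inside (0, 1)", call. = FALSE)
  }
  if (validation_split < 0 || validation_split >= 1) {
    stop("`validation_split` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(optimizer = "adam", learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         k_folds = as.integer(k_folds), seed = as.integer(seed),
         threshold = threshold, validation_split = validation_split),
    class = "mvmdm_train_config"
  )
}

#' Architecture self-check
#'
#' Recomputes the shape traces and parameter counts of the three full-size
#' architectures from their declarative specs and compares them against the
#' package's reference architecture numbers (flatten widths 1280 / 25088 /
#' 193536; totals 88,385 / 3,305,089 with 448 non-trainable / 24,957,985).
#'
#' @return A tibble with one row per route: flatten width, parameter totals,
#'   and whether each matches the reference. Attribute `ok` is `TRUE` iff all
#'   rows match.
#' @export
check_architecture <- function() {
  ref <- tibble::tibble(
    name = c("conv1d_energy", "conv2d_fused", "conv3d_volume"),
    flatten = c(1280L, 25088L, 193536L),
    total = c(88385, 3305089, 24957985),
    non_trainable = c(0, 448, 0)
  )
  got <- purrr::map_dfr(ref$name, function(nm) {
    spec <- model_spec(nm, profile = "paper")
    tr <- shape_trace(spec)
    flat_i <- which(vapply(spec$layers, function(l) l$kind == "flatten",
                           logical(1)))
    pc <- parameter_count(spec)
    tibble::tibble(name = nm, flatten = tr[[flat_i]], total = pc$total,
                   non_trainable = pc$non_trainable)
  })
  out <- dplyr::left_join(got, ref, by = "name",
                          suffix = c("", "_ref"))
  out$matches <- out$flatten == out$flatten_ref &
    out$total == out$total_ref &
    out$non_trainable == out$non_trainable_ref
  attr(out, "ok") <- all(out$matches)
  out
}
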