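#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a trained route model
#'
#' Returns the per-epoch training history in long-friendly wide form.
#'
#' @param x An `mvmdm_model`.
#' @param ... Unused.
#' @return The history tibble (`epoch`, `loss`, `accuracy`, validation
#'   columns when present).
#' @method tidy mvmdm_model
#' @export
tidy.mvmdm_model <- function(x, ...) {
  x$history
}

#' One-row summary of a trained route model
#'
#' @param x An `mvmdm_model`.
#' @param ... Unused.
#' @return A tibble with the route name, parameter total, epochs trained and
#'   final loss/accuracy.
#' @method glance mvmdm_model
#' @export
glance.mvmdm_model <- function(x, ...) {
  pc <- parameter_count(x$spec)
  last <- if (nrow(x$history)) utils::tail(x$history, 1) else
    tibble::tibble(loss = NA_real_, accuracy = NA_real_)
  tibble::tibble(
    route = x$spec$name, profile = x$spec$profile,
    parameters = pc$total, epochs = nrow(x$history),
    loss = last$loss, accuracy = last$accuracy
  )
}

#' Tidy a confusion matrix
#'
#' @param x An `mvmdm_confusion`.
#' @param ... Unused.
#' @return A tibble with columns `TN`, `FP`, `FN`, `TP`.
#' @method tidy mvmdm_confusion
#' @export
tidy.mvmdm_confusion <- function(x, ...) {
  tibble::tibble(TN = x$TN, FP = x$FP, FN = x$FN, TP = x$TP)
}

#' Metrics summary of a confusion matrix
#'
#' @param x An `mvmdm_confusion`.
#' @param ... Unused.
#' @return The [compute_metrics()] tibble.
#' @method glance mvmdm_confusion
#' @export
glance.mvmdm_confusion <- function(x, ...) {
  compute_metrics(x)
}

#' Per-seed summary of a k-fold evaluation
#'
#' @param x An `mvmdm_kfold` tibble from [kfold_evaluate()].
#' @param ... Unused.
#' @return The per-seed tibble of mean accuracy and SD.
#' @method glance mvmdm_kfold
#' @export
glance.mvmdm_kfold <- function(x, ...) {
  attr(x, "by_seed")
}

#' Plot a training history
#'
#' Loss and training accuracy per epoch for one trained route.
#'
#' @param object An `mvmdm_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvmdm_model
#' @export
autoplot.mvmdm_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = object$spec$name, x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class energy profiles
#'
#' Boxplots of per-slice energies by class from an energy feature table, the
#' view in which the class separation of the diagonal-detail energies is
#' assessed.
#'
#' @param features A tibble from [cohort_energy_features()].
#' @return A ggplot object.
#' @export
plot_energy_distribution <- function(features) {
  long <- tidyr::pivot_longer(features, dplyr::starts_with("e_"),
                              names_to = "slice", values_to = "energy")
  long$class <- factor(long$label, c(0, 1), c("healthy", "disease"))
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$energy,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "slice energy (sum of gradient magnitudes)") +
    ggplot2::theme_minimal()
}

#' Plot a k-fold stability table
#'
#' Per-fold held-out accuracy by seed, with the per-seed mean overlaid.
#'
#' @param object An `mvmdm_kfold` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvmdm_kfold
#' @export
autoplot.mvmdm_kfold <- function(object, ...) {
  by_seed <- attr(object, "by_seed")
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$seed), .data$accuracy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = by_seed,
                        ggplot2::aes(factor(.data$seed),
                                     .data$mean_accuracy),
                        colour = "red", size = 3, shape = 18) +
    ggplot2::labs(x = "seed", y = "held-out fold accuracy") +
    ggplot2::theme_minimal()
}
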