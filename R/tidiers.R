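#' Tidy the training history of a fitted network
#'
#' @param x a trained `soma_classifier` or `soma_segmenter`.
#' @param ... unused.
#' @return The per-epoch history tibble.
#' @export
tidy.soma_classifier <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history; train it first")
  x$history
}

#' @rdname tidy.soma_classifier
#' @export
tidy.soma_segmenter <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history; train it first")
  x$history
}

#' One-row summary of a fitted network
#'
#' @param x a trained `soma_classifier` or `soma_segmenter`.
#' @param ... unused.
#' @return A one-row tibble with the parameter count, epochs run, best
#'   epoch, and best validation metric.
#' @export
glance.soma_classifier <- function(x, ...) {
  tibble(n_params = count_params(x),
         epochs = if (is.null(x$history)) 0L else nrow(x$history),
         best_epoch = x$best_epoch %||% NA_integer_,
         best_val_auc = x$best_auc %||% NA_real_)
}

#' @rdname glance.soma_classifier
#' @export
glance.soma_segmenter <- function(x, ...) {
  tibble(n_params = count_params(x),
         epochs = if (is.null(x$history)) 0L else nrow(x$history),
         best_epoch = x$best_epoch %||% NA_integer_,
         best_val_dice = x$best_dice %||% NA_real_)
}

#' Plot a training history
#'
#' Loss and validation metric per epoch, faceted.
#'
#' @param object a trained `soma_classifier` or `soma_segmenter`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.soma_classifier <- function(object, ...) plot_history(tidy(object), "val_auc")

#' @rdname autoplot.soma_classifier
#' @export
autoplot.soma_segmenter <- function(object, ...) plot_history(tidy(object), "val_dice")

plot_history <- function(history, metric) {
  long <- dplyr::bind_rows(
    tibble(epoch = history$epoch, value = history$train_loss,
           series = "training loss"),
    tibble(epoch = history$epoch, value = history[[metric]],
           series = gsub("_", " ", metric))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-region neuron fractions
#'
#' Horizontal bars of whole-brain-normalized neuron fractions per atlas
#' region, the standard summary of a brain-wide mapping run.
#'
#' @param object a tibble from [region_fractions()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_region_fractions <- function(object, ...) {
  df <- dplyr::mutate(object,
                      region = stats::reorder(.data$region_name, .data$fraction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fraction of whole-brain neurons", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
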