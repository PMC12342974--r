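# Tidiers and plots for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted predictor: the per-epoch training log
#' @param x an `sc_model`.
#' @param ... unused.
#' @return tibble with `epoch`, `loss`, `val_auprc`, `lr`.
#' @export
tidy.sc_model <- function(x, ...) x$log

#' One-row summary of a fitted predictor
#' @param x an `sc_model`.
#' @param ... unused.
#' @return tibble with the configuration and final-epoch state.
#' @export
glance.sc_model <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(feature_group = x$feature_group, d_in = x$d_in,
                 n_layers = x$config$n_layers,
                 hidden_dim = x$config$hidden_dim,
                 epochs = nrow(x$log), final_loss = last$loss,
                 final_val_auprc = last$val_auprc, final_lr = last$lr)
}

#' Tidy the meta-model coefficients
#' @param x an `sc_meta`.
#' @param ... unused.
#' @return tibble with `term` and `estimate`.
#' @export
tidy.sc_meta <- function(x, ...) {
  tibble::tibble(term = c("(intercept)", x$groups),
                 estimate = c(x$b, x$w))
}

#' Tidy a cross-validation result
#' @param x an `sc_cv`.
#' @param ... unused.
#' @return tibble of per-fold metrics.
#' @export
tidy.sc_cv <- function(x, ...) tibble::as_tibble(x)

#' Aggregate cross-validation metrics
#' @param x an `sc_cv`.
#' @param ... unused.
#' @return one-row tibble of fold-mean metrics.
#' @export
glance.sc_cv <- function(x, ...) attr(x, "summary")

#' Plot the training trajectory
#'
#' Loss, validation AUPRC and learning rate against epoch, on free y scales.
#'
#' @param object an `sc_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sc_model <- function(object, ...) {
  log <- object$log
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = log$epoch, value = log$loss, what = "loss"),
    tibble::tibble(epoch = log$epoch, value = log$val_auprc,
                   what = "validation AUPRC"),
    tibble::tibble(epoch = log$epoch, value = log$lr, what = "learning rate"))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC and precision-recall curves for a set of predictions
#'
#' @param labels 0/1 vector.
#' @param scores positive-class probabilities.
#' @return a ggplot with the two curves side by side.
#' @export
plot_prediction_curves <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  P <- sum(y == 1); N <- sum(y == 0)
  df <- dplyr::bind_rows(
    tibble::tibble(x = c(0, fp / N), y = c(0, tp / P), curve = "ROC"),
    tibble::tibble(x = c(0, tp / P), y = c(1, tp / (tp + fp)),
                   curve = "Precision-recall"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
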