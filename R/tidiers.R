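#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report into its DRk curve
#'
#' @param x A `pupil_eval`.
#' @param ... Unused.
#' @return Tibble with `k` (pixels) and `rate` (percent).
#' @exportS3Method generics::tidy
tidy.pupil_eval <- function(x, ...) x$drk

#' One-row summary of an evaluation report
#'
#' @param x A `pupil_eval`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pupil_eval <- function(x, ...) {
  tibble(
    source_tag = x$source_tag, n_images = x$n_images,
    dr5 = x$dr5, sigma = x$sigma, lost_frames = x$lost_frames,
    mean_error = mean(x$distances), median_error = median(x$distances)
  )
}

#' Per-epoch training history
#'
#' @param x A `pupil_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pupil_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `pupil_fit`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pupil_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble(
    target = x$target, epochs = nrow(h),
    n_parameters = count_parameters(x$spec),
    final_cost = last$train_cost,
    val_accuracy = last$val_accuracy,
    test_accuracy = last$test_accuracy,
    early_stopped = isTRUE(x$early_stopped)
  )
}

#' Plot the detection-rate curve of an evaluation report
#'
#' Detection rate (percent) against the pixel-error threshold k = 0..10,
#' with the DR5 operating point marked.
#'
#' @param object A `pupil_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pupil_eval <- function(object, ...) {
  df <- object$drk
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = 0:10) +
    ggplot2::labs(
      x = "pixel-error threshold k",
      y = "detection rate DRk (%)",
      title = sprintf("%s: DR5 = %.2f%%, sigma = %.2f px",
                      object$source_tag, object$dr5, object$sigma)
    ) +
    ggplot2::theme_minimal()
}

#' Plot training progress of a fit
#'
#' Validation and test exact-class accuracy per epoch, with the
#' learning-rate stages shaded.
#'
#' @param object A `pupil_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pupil_fit <- function(object, ...) {
  h <- object$history
  long <- tibble(
    epoch = rep(h$epoch, 2),
    accuracy = c(h$val_accuracy, h$test_accuracy),
    set = rep(c("validation", "test"), each = nrow(h))
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                               colour = .data$set, shape = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "exact-class accuracy (%)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
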