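#' Euclidean pixel error between two pupil centers
#'
#' @param ideal,detected Annotations: named vectors `c(cx, cy)` or data
#'   frames with `cx`, `cy` columns (vectorized).
#' @return Euclidean distance(s) in pixels.
#' @export
#' @examples
#' pixel_error(c(cx = 0, cy = 0), c(cx = 3, cy = 4))  # 5
pixel_error <- function(ideal, detected) {
  gx <- if (is.data.frame(ideal)) ideal$cx else ideal[["cx"]]
  gy <- if (is.data.frame(ideal)) ideal$cy else ideal[["cy"]]
  dx <- if (is.data.frame(detected)) detected$cx else detected[["cx"]]
  dy <- if (is.data.frame(detected)) detected$cy else detected[["cy"]]
  sqrt((gx - dx)^2 + (gy - dy)^2)
}

#' Detection rate at k pixels
#'
#' Percentage of images whose pixel error is less than or equal to `k`
#' (inclusive threshold).
#'
#' @param distances Per-image pixel errors.
#' @param k Threshold in pixels (>= 0).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' detection_rate(c(1, 2, 3, 10), 5)  # 75
detection_rate <- function(distances, k) {
  if (length(distances) == 0) pg_stop("empty distance list", "count")
  if (k < 0) pg_stop("k must be >= 0", "config")
  100 * mean(distances <= k)
}

#' Dispersion of the pixel-error distribution
#'
#' Population standard deviation (divisor N) of the per-image Euclidean
#' errors; a proxy for on-screen cursor stability.
#'
#' @param distances Per-image pixel errors.
#' @return Standard deviation in pixels.
#' @export
sigma_px <- function(distances) {
  if (length(distances) == 0) pg_stop("empty distance list", "count")
  sqrt(mean((distances - mean(distances))^2))
}

new_eval_report <- function(distances, source_tag) {
  ks <- 0:10
  structure(list(
    distances = distances,
    drk = tibble(k = ks,
                 rate = vapply(ks, function(k) detection_rate(distances, k),
                               numeric(1))),
    dr5 = detection_rate(distances, 5),
    sigma = sigma_px(distances),
    n_images = length(distances),
    lost_frames = sum(distances > 10),
    source_tag = source_tag
  ), class = "pupil_eval")
}

#' Predict pupil centers for a dataset
#'
#' @param detector A detector built with [xy_detector()] or
#'   [lowres_detector()].
#' @param images List of image matrices.
#' @return Tibble with integer `cx`, `cy` per image.
#' @export
predict_centers <- function(detector, images) {
  stopifnot(inherits(detector, "pupil_detector"))
  if (detector$kind == "xy") {
    tibble(cx = predict_classes(detector$x$params, images) - 1L,
           cy = predict_classes(detector$y$params, images) - 1L)
  } else {
    w <- detector$fit$spec[[1]]$w
    h <- detector$fit$spec[[1]]$h
    class_to_coord(predict_classes(detector$fit$params, images), w, h)
  }
}

#' Bundle trained coordinate classifiers into a detector
#'
#' `xy_detector()` pairs the x- and y-coordinate fits of the
#' high-resolution system; `lowres_detector()` wraps a low-resolution
#' pixel-class fit.
#'
#' @param x_fit,y_fit `pupil_fit` objects trained with targets `"x"` and
#'   `"y"`.
#' @return A `pupil_detector`.
#' @export
xy_detector <- function(x_fit, y_fit) {
  stopifnot(inherits(x_fit, "pupil_fit"), inherits(y_fit, "pupil_fit"))
  structure(list(kind = "xy", x = x_fit, y = y_fit),
            class = "pupil_detector")
}

#' @rdname xy_detector
#' @param fit A `pupil_fit` trained with target `"cell"`.
#' @export
lowres_detector <- function(fit) {
  stopifnot(inherits(fit, "pupil_fit"))
  structure(list(kind = "lowres", fit = fit), class = "pupil_detector")
}

#' Evaluate a detector on a labeled dataset
#'
#' Predicts every image, computes the per-image Euclidean pixel error
#' against the ground truth and summarizes it: the DRk curve at integer
#' k = 0..10, the k = 5 operating point DR5, the dispersion sigma
#' (population standard deviation of the errors) and the number of lost
#' frames (error > 10 pixels).
#'
#' @param detector A `pupil_detector`.
#' @param samples Dataset tibble with `image`, `cx`, `cy`.
#' @param source_tag Label for the report; defaults to the dataset's tag.
#' @return A `pupil_eval` report.
#' @export
evaluate_detector <- function(detector, samples, source_tag = NULL) {
  if (nrow(samples) == 0) pg_stop("empty evaluation set", "count")
  pred <- predict_centers(detector, samples$image)
  d <- pixel_error(samples[, c("cx", "cy")], pred)
  tag <- source_tag %||%
    (if ("source_tag" %in% names(samples)) samples$source_tag[1] else "data")
  new_eval_report(d, tag)
}

#' @rdname evaluate_detector
#' @param x_fit,y_fit Coordinate fits, as in [xy_detector()].
#' @export
evaluate_xy <- function(x_fit, y_fit, samples, source_tag = NULL) {
  evaluate_detector(xy_detector(x_fit, y_fit), samples, source_tag)
}

#' Pool evaluation reports over datasets
#'
#' Concatenates the raw per-image distance lists and recomputes every
#' statistic from the pooled list — never an average of per-dataset rates —
#' so datasets weigh by their image counts.
#'
#' @param reports List of `pupil_eval` reports.
#' @return A pooled `pupil_eval`.
#' @export
pooled_report <- function(reports) {
  if (inherits(reports, "pupil_eval")) reports <- list(reports)
  if (length(reports) == 0) pg_stop("no reports to pool", "count")
  stopifnot(all(vapply(reports, inherits, logical(1), "pupil_eval")))
  d <- unlist(lapply(reports, `[[`, "distances"))
  new_eval_report(d, "pooled")
}

#' Smooth a pupil-center track over consecutive frames
#'
#' For each frame, looks at the centers inside an odd window centered on
#' it (truncated at the ends of the track), drops neighbors whose distance
#' to the coordinate-wise window median exceeds `outlier_threshold`, and
#' replaces the frame's center with the rounded mean of the survivors.
#' Intended to suppress occasional lost frames in real-time tracks.
#'
#' @param centers Tibble or data frame with `cx`, `cy`, in time order.
#' @param window Odd window length (1 = identity).
#' @param outlier_threshold Rejection radius in pixels.
#' @return Tibble with smoothed integer `cx`, `cy`.
#' @export
temporal_smooth <- function(centers, window = 3, outlier_threshold = 5) {
  if (window < 1 || window %% 2 == 0) {
    pg_stop("window must be odd and >= 1", "config")
  }
  n <- nrow(centers)
  half <- (window - 1) / 2
  out_cx <- integer(n)
  out_cy <- integer(n)
  for (i in seq_len(n)) {
    sel <- max(1, i - half):min(n, i + half)
    wx <- centers$cx[sel]
    wy <- centers$cy[sel]
    md <- c(median(wx), median(wy))
    keep <- sqrt((wx - md[1])^2 + (wy - md[2])^2) <= outlier_threshold
    if (!any(keep)) keep <- rep(TRUE, length(sel)) # degenerate window
    out_cx[i] <- as.integer(round_half_up(mean(wx[keep])))
    out_cy[i] <- as.integer(round_half_up(mean(wy[keep])))
  }
  tibble(cx = out_cx, cy = out_cy)
}

#' @export
print.pupil_eval <- function(x, ...) {
  cat("<pupil_eval> ", x$source_tag, ": n = ", x$n_images,
      sprintf(", DR5 = %.2f%%, sigma = %.2f px, lost frames = %d\n",
              x$dr5, x$sigma, x$lost_frames), sep = "")
  invisible(x)
}
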