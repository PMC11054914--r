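#' Run a network forward on one image
#'
#' Feedforward inference: ReLU after every hidden dense or convolutional
#' layer, max over each 2x2 block in pooling layers, and a numerically
#' stabilized softmax at the output, so the result is a probability
#' distribution over position classes.
#'
#' @param params A `network_params` object (see [init_params()]).
#' @param img A height x width matrix matching the spec's input size,
#'   intensities in \[0, 1\].
#' @return Numeric probability vector (sums to 1).
#' @export
forward <- function(params, img) {
  stopifnot(inherits(params, "network_params"))
  if (!is.matrix(img)) pg_stop("image must be a matrix", "shape")
  .nn_forward_cpp(unclass(params$spec), params$layers, img)
}

#' Decode a probability vector to a coordinate
#'
#' Picks the class with the highest probability; ties break toward the
#' lowest index. Classes are 1-based internally, so class k maps to the
#' 0-based coordinate (or grid cell) k - 1.
#'
#' @param p Probability vector.
#' @return Integer 0-based coordinate.
#' @export
#' @examples
#' decode_coordinate(c(0.1, 0.2, 0.7))  # 2
decode_coordinate <- function(p) {
  if (length(p) == 0) pg_stop("empty probability vector", "range")
  as.integer(which.max(p) - 1L)
}

#' Predict a pupil center with the x/y classifier pair
#'
#' Runs both coordinate networks on the same image and decodes each
#' marginal: the x network's argmax column and the y network's argmax row
#' together give the pupil center.
#'
#' @param x_params,y_params `network_params` for the x and y classifiers.
#' @param img Input image matrix.
#' @return Named integer vector `c(cx, cy)`.
#' @export
predict_center <- function(x_params, y_params, img) {
  c(cx = decode_coordinate(forward(x_params, img)),
    cy = decode_coordinate(forward(y_params, img)))
}

# batch argmax classes (1-based) for a list of images
predict_classes <- function(params, images) {
  .nn_predict_cpp(unclass(params$spec), params$layers, images)
}
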