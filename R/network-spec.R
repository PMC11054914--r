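#' Network specifications
#'
#' A `network_spec` is an ordered list of declarative layer descriptors:
#' `input(h, w)`, `conv(kh, kw, maps, connectivity)`, `maxpool` (2x2,
#' stride 2), `dense(n)` (ReLU) and `softmax(n)`. Convolutions are valid
#' (no padding, stride 1); `connectivity` is either `"full"` (every feature
#' map sees every input map) or `"per_map"` (depthwise: map m convolves
#' only input map m).
#'
#' @name network_spec
NULL

new_spec <- function(layers) structure(layers, class = "network_spec")

layer_input <- function(h, w) {
  list(type = "input", h = as.integer(h), w = as.integer(w))
}
layer_conv <- function(kh, kw, maps, connectivity = c("full", "per_map")) {
  connectivity <- match.arg(connectivity)
  list(type = "conv", kh = as.integer(kh), kw = as.integer(kw),
       maps = as.integer(maps), connectivity = connectivity)
}
layer_maxpool <- function() list(type = "maxpool")
layer_dense <- function(n) list(type = "dense", n = as.integer(n))
layer_softmax <- function(n) list(type = "softmax", n = as.integer(n))

#' Low-resolution position classifier specification
#'
#' Fully-connected classifier for 20x15 images: the 300 input intensities
#' feed two hidden ReLU layers of 100 neurons each and a 300-class softmax
#' output, one class per pixel position. Totals exactly 70,500 trainable
#' parameters.
#'
#' @return A `network_spec`.
#' @export
#' @examples
#' count_parameters(lowres_spec())
lowres_spec <- function() {
  new_spec(list(
    layer_input(15, 20),
    layer_dense(100),
    layer_dense(100),
    layer_softmax(300)
  ))
}

#' Slim convolutional coordinate-classifier specification
#'
#' The high-resolution system localizes the pupil center in a 320x240
#' image with two independent slim CNNs, one per coordinate, each a
#' classifier over pixel columns (x, 320 classes) or rows (y, 240
#' classes). Both share the backbone: four valid convolutions with 5
#' feature maps (kernels 5x5, 5x5, 4x4, 4x4), each followed by 2x2
#' max-pooling; after the first convolution the maps are connected
#' per-map (depthwise). The head is a ReLU dense layer (640 for x, 480
#' for y) and the coordinate softmax. The x network totals exactly
#' 858,990 trainable parameters.
#'
#' @param axis `"x"` (columns) or `"y"` (rows).
#' @return A `network_spec`.
#' @export
#' @examples
#' count_parameters(coordinate_cnn_spec("x"))
coordinate_cnn_spec <- function(axis = c("x", "y")) {
  axis <- match.arg(axis)
  new_spec(list(
    layer_input(240, 320),
    layer_conv(5, 5, 5, "full"),
    layer_maxpool(),
    layer_conv(5, 5, 5, "per_map"),
    layer_maxpool(),
    layer_conv(4, 4, 5, "per_map"),
    layer_maxpool(),
    layer_conv(4, 4, 5, "per_map"),
    layer_maxpool(),
    layer_dense(if (axis == "x") 640L else 480L),
    layer_softmax(if (axis == "x") 320L else 240L)
  ))
}

#' Propagate feature-map shapes through a specification
#'
#' Valid convolution shrinks each spatial axis by `kernel - 1`; 2x2
#' pooling halves it. Spatial shapes are reported as
#' `c(maps, width, height)`; dense and softmax layers as their neuron
#' count.
#'
#' @param spec A `network_spec`.
#' @return A list with one shape per layer (input included).
#' @export
#' @examples
#' infer_shapes(coordinate_cnn_spec("x"))[[2]]  # 5 x 316 x 236
infer_shapes <- function(spec) {
  if (length(spec) < 2 || spec[[1]]$type != "input" ||
      spec[[length(spec)]]$type != "softmax") {
    pg_stop("spec must start with input and end with softmax", "config")
  }
  h <- spec[[1]]$h
  w <- spec[[1]]$w
  maps <- 1L
  spatial <- TRUE
  shapes <- list(c(maps = maps, w = w, h = h))
  for (ly in spec[-1]) {
    if (ly$type == "conv") {
      if (!spatial) pg_stop("conv after a dense layer", "config")
      h <- h - ly$kh + 1L
      w <- w - ly$kw + 1L
      if (h < 1 || w < 1) {
        pg_stop("conv kernel larger than its feature map", "config")
      }
      if (ly$connectivity == "per_map" && ly$maps != maps) {
        pg_stop("per-map conv must keep the map count", "config")
      }
      maps <- ly$maps
      shapes <- c(shapes, list(c(maps = maps, w = w, h = h)))
    } else if (ly$type == "maxpool") {
      if (!spatial) pg_stop("pool after a dense layer", "config")
      if (h %% 2 || w %% 2) {
        pg_stop("2x2 pooling needs even feature-map sides", "config")
      }
      h <- h %/% 2L
      w <- w %/% 2L
      shapes <- c(shapes, list(c(maps = maps, w = w, h = h)))
    } else if (ly$type %in% c("dense", "softmax")) {
      spatial <- FALSE
      shapes <- c(shapes, list(ly$n))
    } else {
      pg_stop(paste0("unknown layer type ", ly$type), "config")
    }
  }
  shapes
}

# number of scalar inputs feeding layer i (flattened for dense layers)
layer_fanins <- function(spec) {
  shapes <- infer_shapes(spec)
  vapply(seq_along(spec), function(i) {
    if (i == 1) return(0L)
    s <- shapes[[i - 1]]
    as.integer(if (length(s) == 3) prod(s) else s)
  }, integer(1))
}

#' Count trainable parameters
#'
#' Sums weights and biases layer by layer: a dense or softmax layer with
#' `n_in` inputs and `n_out` neurons holds `n_in * n_out + n_out`
#' parameters; a fully connected convolution `maps * (kh * kw * n_in_maps
#' + 1)`; a per-map convolution `maps * (kh * kw + 1)`; pooling holds
#' none.
#'
#' @param spec A `network_spec`.
#' @return Integer parameter total.
#' @export
#' @examples
#' count_parameters(lowres_spec())          # 70500
#' count_parameters(coordinate_cnn_spec("x"))  # 858990
count_parameters <- function(spec) {
  shapes <- infer_shapes(spec)
  total <- 0
  maps_in <- 1L
  for (i in seq_along(spec)[-1]) {
    ly <- spec[[i]]
    if (ly$type == "conv") {
      total <- total + if (ly$connectivity == "per_map") {
        ly$maps * (ly$kh * ly$kw + 1)
      } else {
        ly$maps * (ly$kh * ly$kw * maps_in + 1)
      }
      maps_in <- ly$maps
    } else if (ly$type %in% c("dense", "softmax")) {
      s <- shapes[[i - 1]]
      n_in <- if (length(s) == 3) prod(s) else s
      total <- total + n_in * ly$n + ly$n
    }
  }
  as.integer(total)
}

#' Initialize network parameters
#'
#' Weights are drawn from a zero-mean Gaussian with standard deviation
#' `sqrt(2 / fan_in)` (He scaling, where `fan_in` is the number of inputs
#' feeding each neuron): each ReLU zeroes about half its input variance,
#' so the factor 2 keeps activation magnitudes stable through the layer
#' stack, which matters for the short staged schedules used here. Biases
#' start at zero. Fully reproducible from `seed`.
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed.
#' @return A `network_params` object: the spec, a list of `W`/`b` arrays
#'   per trainable layer, and the seed.
#' @export
init_params <- function(spec, seed = 1) {
  infer_shapes(spec) # validates
  fanins <- layer_fanins(spec)
  with_seed(seed, {
    layers <- list()
    maps_in <- 1L
    for (i in seq_along(spec)[-1]) {
      ly <- spec[[i]]
      if (ly$type == "conv") {
        if (ly$connectivity == "per_map") {
          fan <- ly$kh * ly$kw
          W <- array(rnorm(fan * ly$maps, 0, sqrt(2 / fan)),
                     dim = c(ly$kh, ly$kw, ly$maps))
        } else {
          fan <- ly$kh * ly$kw * maps_in
          W <- array(rnorm(fan * ly$maps, 0, sqrt(2 / fan)),
                     dim = c(ly$kh, ly$kw, maps_in, ly$maps))
        }
        layers[[length(layers) + 1]] <- list(W = W,
                                             b = numeric(ly$maps))
        maps_in <- ly$maps
      } else if (ly$type %in% c("dense", "softmax")) {
        n_in <- fanins[i]
        W <- matrix(rnorm(ly$n * n_in, 0, sqrt(2 / n_in)), ly$n, n_in)
        layers[[length(layers) + 1]] <- list(W = W, b = numeric(ly$n))
      }
    }
    structure(list(spec = spec, layers = layers, seed = as.integer(seed)),
              class = "network_params")
  })
}

#' @export
print.network_spec <- function(x, ...) {
  shapes <- infer_shapes(x)
  cat("<network_spec> ", length(x), " layers, ",
      format(count_parameters(x), big.mark = ","), " parameters\n",
      sep = "")
  for (i in seq_along(x)) {
    s <- shapes[[i]]
    dims <- if (length(s) == 3) paste(s, collapse = " x ") else s
    cat(sprintf("  %d: %-8s -> %s\n", i, x[[i]]$type, dims))
  }
  invisible(x)
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> seed ", x$seed, ", ",
      format(count_parameters(x$spec), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}
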