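# Small fixtures shared across the suite; everything is generated in code.

# toy network touching every layer kind (full conv, pool, per-map conv,
# dense, softmax); 57 parameters
toy_conv_spec <- function() {
  pupilgrid:::new_spec(list(
    pupilgrid:::layer_input(6, 6),
    pupilgrid:::layer_conv(3, 3, 2, "full"),
    pupilgrid:::layer_maxpool(),
    pupilgrid:::layer_conv(2, 2, 2, "per_map"),
    pupilgrid:::layer_dense(4),
    pupilgrid:::layer_softmax(3)
  ))
}

# tiny dense net (input 1x4 -> dense 2 -> softmax 3) for arithmetic oracles
toy_dense_spec <- function() {
  pupilgrid:::new_spec(list(
    pupilgrid:::layer_input(1, 4),
    pupilgrid:::layer_dense(2),
    pupilgrid:::layer_softmax(3)
  ))
}

manual_params <- function(spec, layers, seed = 1) {
  p <- init_params(spec, seed)
  for (i in seq_along(layers)) p$layers[[i]] <- layers[[i]]
  p
}

# pure-R forward pass for toy dense nets: the independent arithmetic oracle
dense_oracle <- function(layers, x) {
  for (i in seq_along(layers)) {
    z <- drop(layers[[i]]$W %*% x) + layers[[i]]$b
    x <- if (i < length(layers)) pmax(z, 0) else {
      e <- exp(z - max(z))
      e / sum(e)
    }
  }
  x
}

# parameters for finite-difference checks: moderate weights plus nonzero
# random biases, so no ReLU pre-activation sits at its kink, no layer is
# fully dead, and softmax probabilities stay far above the cross-entropy
# clamp -- the loss is smooth there and central differences are meaningful
fd_test_params <- function(spec, seed) {
  p <- init_params(spec, seed)
  withr::with_seed(seed + 1000L, {
    for (i in seq_along(p$layers)) {
      p$layers[[i]]$W <- p$layers[[i]]$W * 0.6
      p$layers[[i]]$b <- rnorm(length(p$layers[[i]]$b), 0, 0.2)
    }
  })
  p
}

# central finite-difference gradient of the cross-entropy loss
fd_gradients <- function(params, img, target, h = 1e-5) {
  loss_at <- function(layers) {
    p <- pupilgrid:::.nn_forward_cpp(unclass(params$spec), layers, img)
    -log(max(p[target], 1e-12))
  }
  lapply(seq_along(params$layers), function(li) {
    out <- params$layers[[li]]
    for (nm in c("W", "b")) {
      arr <- params$layers[[li]][[nm]]
      g <- arr
      for (j in seq_along(arr)) {
        lp <- params$layers
        lp[[li]][[nm]][j] <- arr[j] + h
        f1 <- loss_at(lp)
        lp[[li]][[nm]][j] <- arr[j] - h
        f0 <- loss_at(lp)
        g[j] <- (f1 - f0) / (2 * h)
      }
      out[[nm]] <- g
    }
    out
  })
}

# mean intensity inside the pupil ellipse and over an iris annulus ring
pupil_iris_means <- function(scene, img) {
  w <- scene$width
  h <- scene$height
  xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
  yg <- matrix(0:(h - 1), h, w)
  ctr <- scene$pupil_center
  dx <- xg - ctr[["cx"]]
  dy <- yg - ctr[["cy"]]
  ang <- scene$pupil_angle
  a <- scene$pupil_axes[["a"]]
  b <- scene$pupil_axes[["b"]]
  u <- cos(ang) * dx + sin(ang) * dy
  v <- -sin(ang) * dx + cos(ang) * dy
  e <- sqrt((u / a)^2 + (v / b)^2)
  inside <- e <= 0.8
  ring <- e >= 1.5 & e <= 2.2 &
    sqrt(dx^2 + dy^2) <= scene$iris_radius * 0.95
  list(pupil = mean(img[inside]), iris = mean(img[ring]),
       any_inside = any(inside), any_ring = any(ring))
}
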