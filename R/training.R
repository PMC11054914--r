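#' Training configuration
#'
#' Bundles the staged learning-rate schedule and the remaining training
#' hyperparameters. The defaults are the reference protocol: eta = 0.1 for
#' 20 epochs, then 0.01 for 10, 0.001 for 5 and 0.0001 for 3 (38 epochs in
#' all), mini-batches of 10, weight-decay strength lambda = 0.1, and an
#' 80/10/10 train/validation/test split.
#'
#' @param schedule A data frame with columns `lr` and `epochs`, run in
#'   order.
#' @param batch_size Mini-batch size (>= 1).
#' @param lambda L2 weight-decay strength (>= 0); biases are exempt.
#' @param split Named fractions `c(train, val, test)` summing to 1.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param patience Optional early-stopping patience in epochs on
#'   validation accuracy; `NULL` (default) runs the fixed schedule and
#'   returns the final-epoch parameters.
#' @return A `train_config` object.
#' @export
#' @examples
#' train_config(schedule = data.frame(lr = 0.1, epochs = 3))
train_config <- function(schedule = data.frame(
                           lr = c(0.1, 0.01, 0.001, 0.0001),
                           epochs = c(20L, 10L, 5L, 3L)),
                         batch_size = 10, lambda = 0.1,
                         split = c(train = 0.8, val = 0.1, test = 0.1),
                         seed = 1, patience = NULL) {
  schedule <- as_tibble(schedule)
  if (!all(c("lr", "epochs") %in% names(schedule)) ||
      any(schedule$lr <= 0) || any(schedule$epochs < 1)) {
    pg_stop("schedule needs positive `lr` and `epochs` >= 1", "config")
  }
  if (batch_size < 1) pg_stop("batch_size must be >= 1", "config")
  if (lambda < 0) pg_stop("lambda must be >= 0", "config")
  if (length(split) != 3 || abs(sum(split) - 1) > 1e-9 || any(split < 0)) {
    pg_stop("split fractions must be three non-negatives summing to 1",
            "config")
  }
  structure(list(schedule = schedule,
                 batch_size = as.integer(batch_size),
                 lambda = lambda, split = split,
                 seed = as.integer(seed), patience = patience),
            class = "train_config")
}

#' Split a dataset into train / validation / test parts
#'
#' Shuffles under `seed`, then takes `round(n * f)` samples for the
#' validation and test parts and assigns the remainder to the training
#' part, giving a disjoint, exhaustive partition.
#'
#' @param samples Dataset tibble.
#' @param fractions `c(train, val, test)` summing to 1.
#' @param seed Integer seed.
#' @return A list of tibbles `train`, `val`, `test`.
#' @export
#' @examples
#' ds <- generate_dataset(10, "easy", 20, 15, seed = 1)
#' vapply(split_dataset(ds, c(0.8, 0.1, 0.1), 1), nrow, integer(1))
split_dataset <- function(samples, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  n <- nrow(samples)
  if (n < 3) pg_stop("need at least 3 samples to split", "count")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions < 0)) {
    pg_stop("fractions must be three non-negatives summing to 1", "config")
  }
  n_val <- round(n * fractions[2])
  n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  if (n_train < 1) pg_stop("degenerate split: empty training set", "config")
  idx <- with_seed(seed, sample.int(n))
  list(train = samples[idx[seq_len(n_train)], ],
       val = samples[idx[n_train + seq_len(n_val)], ],
       test = samples[idx[n_train + n_val + seq_len(n_test)], ])
}

#' Cross-entropy cost of one prediction
#'
#' `-log p\[target\]`, with the probability clamped below at 1e-12 so a
#' confidently wrong prediction yields a large finite cost rather than an
#' infinity.
#'
#' @param p Probability vector.
#' @param target_class 1-based true class index.
#' @return Non-negative cost.
#' @export
#' @examples
#' cross_entropy(rep(1 / 300, 300), 17)  # log(300)
cross_entropy <- function(p, target_class) {
  if (target_class < 1 || target_class > length(p)) {
    pg_stop("target class out of range", "range")
  }
  -log(max(p[target_class], 1e-12))
}

#' Add the L2 weight-decay term to a data cost
#'
#' The regularized objective is `data_cost + lambda / (2 n_train) *
#' sum(w^2)` over all weights; biases are excluded.
#'
#' @param data_cost Unregularized cost.
#' @param params `network_params`.
#' @param lambda Decay strength.
#' @param n_train Training-set size.
#' @return The regularized cost.
#' @export
regularized_cost <- function(data_cost, params, lambda, n_train) {
  if (lambda < 0) pg_stop("lambda must be >= 0", "config")
  wsum <- sum(vapply(params$layers, function(l) sum(l$W^2), numeric(1)))
  data_cost + lambda / (2 * n_train) * wsum
}

# target extractor: 1-based class per sample row
make_target_fn <- function(target, spec) {
  w <- spec[[1]]$w
  h <- spec[[1]]$h
  switch(target,
    cell = function(d) coord_to_class(d$cx, d$cy, w, h),
    x = function(d) as.integer(d$cx) + 1L,
    y = function(d) as.integer(d$cy) + 1L,
    pg_stop("target must be one of 'cell', 'x', 'y'", "config")
  )
}

apply_update <- function(layers, grads, eta, lambda, n_train) {
  decay <- 1 - eta * lambda / n_train
  for (i in seq_along(layers)) {
    layers[[i]]$W <- decay * layers[[i]]$W - eta * grads[[i]]$W
    layers[[i]]$b <- layers[[i]]$b - eta * grads[[i]]$b
  }
  layers
}

#' One stochastic-gradient-descent step
#'
#' Backpropagates the softmax/cross-entropy objective through the network
#' for one mini-batch, averages the gradients over the batch and applies
#' the update `w <- (1 - eta * lambda / n_train) * w - eta * grad_w`
#' (biases without the decay factor).
#'
#' @param params `network_params`.
#' @param images List of image matrices (the mini-batch).
#' @param targets 1-based class index per image.
#' @param eta Learning rate.
#' @param lambda Weight-decay strength.
#' @param n_train Training-set size (scales the decay).
#' @return Updated `network_params`, with the mean batch cross-entropy in
#'   `attr(, "batch_cost")`.
#' @export
sgd_step <- function(params, images, targets, eta, lambda, n_train) {
  if (length(images) == 0) pg_stop("empty mini-batch", "count")
  res <- .nn_batch_grad_cpp(unclass(params$spec), params$layers, images,
                            as.integer(targets), TRUE)
  params$layers <- apply_update(params$layers, res$grads, eta, lambda,
                                n_train)
  attr(params, "batch_cost") <- res$loss
  params
}

dataset_accuracy <- function(params, images, targets) {
  if (length(images) == 0) return(NA_real_)
  cls <- predict_classes(params, images)
  100 * mean(cls == targets)
}

#' Train a position classifier
#'
#' Mini-batch SGD over the staged learning-rate schedule: each epoch
#' re-shuffles the training set, iterates it in mini-batches, then records
#' the epoch's mean regularized cost and the exact-class accuracy on the
#' validation and test sets. With `patience` set, training stops once
#' validation accuracy has not improved for that many epochs and the
#' best-validation parameters are returned; otherwise the full schedule
#' runs and the final-epoch parameters are returned. The whole run is
#' deterministic given `(spec, data, config)`.
#'
#' @param spec A `network_spec`.
#' @param data Either a dataset tibble (split internally with
#'   `config$split` and `config$seed`) or a list with `train`, `val`,
#'   `test` tibbles.
#' @param target `"cell"` (row-major pixel class, low-res classifier),
#'   `"x"` (column class) or `"y"` (row class).
#' @param config A [train_config()].
#' @param quiet Suppress per-epoch progress lines.
#' @return A `pupil_fit`: list with `params` (`network_params`), `history`
#'   (per-epoch tibble: `epoch`, `stage`, `lr`, `train_cost`,
#'   `val_accuracy`, `test_accuracy`), `spec`, `config`, `target`.
#' @export
train_network <- function(spec, data, target = c("cell", "x", "y"),
                          config = train_config(), quiet = TRUE) {
  target <- match.arg(target)
  stopifnot(inherits(config, "train_config"))
  if (is.data.frame(data)) {
    data <- split_dataset(data, config$split, config$seed)
  }
  if (!all(c("train", "val", "test") %in% names(data)) ||
      nrow(data$train) == 0) {
    pg_stop("data must provide non-empty train plus val/test parts",
            "config")
  }
  tf <- make_target_fn(target, spec)
  tr_img <- data$train$image
  tr_y <- tf(data$train)
  va_img <- data$val$image
  va_y <- if (nrow(data$val)) tf(data$val) else integer(0)
  te_img <- data$test$image
  te_y <- if (nrow(data$test)) tf(data$test) else integer(0)

  n_train <- length(tr_img)
  params <- init_params(spec, config$seed)
  uspec <- unclass(spec)

  history <- list()
  best <- list(acc = -Inf, params = params, since = 0L)
  epoch <- 0L
  stopped <- FALSE
  with_seed(config$seed + 1L, {
    for (stage in seq_len(nrow(config$schedule))) {
      if (stopped) break
      eta <- config$schedule$lr[stage]
      for (ep in seq_len(config$schedule$epochs[stage])) {
        epoch <- epoch + 1L
        perm <- sample.int(n_train)
        costs <- c()
        for (start in seq(1, n_train, by = config$batch_size)) {
          sel <- perm[start:min(start + config$batch_size - 1, n_train)]
          res <- .nn_batch_grad_cpp(uspec, params$layers, tr_img[sel],
                                    tr_y[sel], TRUE)
          params$layers <- apply_update(params$layers, res$grads, eta,
                                        config$lambda, n_train)
          costs <- c(costs, res$loss)
        }
        train_cost <- regularized_cost(mean(costs), params, config$lambda,
                                       n_train)
        val_acc <- dataset_accuracy(params, va_img, va_y)
        test_acc <- dataset_accuracy(params, te_img, te_y)
        history[[epoch]] <- tibble(
          epoch = epoch, stage = stage, lr = eta,
          train_cost = train_cost, val_accuracy = val_acc,
          test_accuracy = test_acc
        )
        if (!quiet) {
          message(sprintf(
            "epoch %3d (eta %.4g): cost %.4f, val %.1f%%, test %.1f%%",
            epoch, eta, train_cost, val_acc, test_acc))
        }
        if (!is.null(config$patience) && !is.na(val_acc)) {
          if (val_acc > best$acc) {
            best <- list(acc = val_acc, params = params, since = 0L)
          } else {
            best$since <- best$since + 1L
            if (best$since >= config$patience) {
              stopped <- TRUE
              break
            }
          }
        }
      }
    }
  })
  final <- if (!is.null(config$patience) && best$acc > -Inf) {
    best$params
  } else {
    params
  }
  structure(list(params = final, history = dplyr::bind_rows(history),
                 spec = spec, config = config, target = target,
                 early_stopped = stopped),
            class = "pupil_fit")
}

#' @export
print.pupil_fit <- function(x, ...) {
  h <- x$history
  cat("<pupil_fit> target '", x$target, "', ", nrow(h), " epochs, ",
      format(count_parameters(x$spec), big.mark = ","), " parameters\n",
      sep = "")
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final: cost %.4f, val %.1f%%, test %.1f%%\n",
                last$train_cost, last$val_accuracy, last$test_accuracy))
  }
  invisible(x)
}
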