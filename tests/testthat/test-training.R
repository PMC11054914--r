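test_that("splitting rounds val/test and gives the remainder to train", {
  ds <- generate_dataset(100, "easy", 20, 15, seed = 1)
  sp <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 2)
  expect_identical(vapply(sp, nrow, integer(1)),
                   c(train = 80L, val = 10L, test = 10L))
  ds10 <- ds[1:10, ]
  sp10 <- split_dataset(ds10, c(0.8, 0.1, 0.1), seed = 2)
  expect_identical(vapply(sp10, nrow, integer(1)),
                   c(train = 8L, val = 1L, test = 1L))
})

test_that("the split is a disjoint, exhaustive partition", {
  ds <- generate_dataset(37, "easy", 20, 15, seed = 5)
  ds$id <- seq_len(37)
  sp <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 9)
  ids <- c(sp$train$id, sp$val$id, sp$test$id)
  expect_identical(sort(ids), 1:37)
  expect_identical(anyDuplicated(ids), 0L)
  # same seed reproduces the same partition
  sp2 <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 9)
  expect_identical(sp$train$id, sp2$train$id)
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(c(0, 1, 0), 2), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), 1), log(2))
  expect_equal(cross_entropy(rep(1 / 300, 300), 123), log(300),
               tolerance = 1e-12)
  expect_true(is.finite(cross_entropy(c(1, 0), 2))) # clamped, not Inf
  expect_error(cross_entropy(c(0.5, 0.5), 3),
               class = "pupilgrid_range_error")
})

test_that("the weight-decay term is lambda/(2n) * sum of squared weights", {
  p <- init_params(toy_dense_spec(), 1)
  expect_equal(regularized_cost(1.5, p, 0, 10), 1.5)
  z <- p
  for (i in seq_along(z$layers)) z$layers[[i]]$W[] <- 0
  expect_equal(regularized_cost(1.5, z, 0.7, 10), 1.5)
  one <- z
  one$layers[[1]]$W[1, 1] <- 2
  expect_equal(regularized_cost(1.0, one, 0.1, 10), 1.0 + 0.1 / 20 * 4)
})

test_that("backprop matches central finite differences for every layer kind", {
  for (seed in c(2, 3)) {
    p <- fd_test_params(toy_conv_spec(), seed)
    set.seed(seed)
    img <- matrix(runif(36), 6, 6)
    target <- sample(3, 1)
    got <- pupilgrid:::.nn_batch_grad_cpp(unclass(p$spec), p$layers,
                                          list(img), target, TRUE)$grads
    want <- fd_gradients(p, img, target)
    for (li in seq_along(want)) {
      for (nm in c("W", "b")) {
        denom <- pmax(abs(want[[li]][[nm]]) + abs(got[[li]][[nm]]), 1e-4)
        expect_lt(max(abs(want[[li]][[nm]] - got[[li]][[nm]]) / denom),
                  1e-5)
      }
    }
  }
})

test_that("the SGD update applies Eq-style parameter minus rate times gradient", {
  spec <- toy_dense_spec()
  layers <- list(
    list(W = matrix(1.0, 2, 4), b = c(0, 0)),
    list(W = matrix(0.5, 3, 2), b = c(0, 0, 0))
  )
  p <- manual_params(spec, layers)
  grads <- list(
    list(W = matrix(0.5, 2, 4), b = c(0, 0)),
    list(W = matrix(0, 3, 2), b = c(0, 0, 0))
  )
  up <- pupilgrid:::apply_update(p$layers, grads, eta = 0.1, lambda = 0,
                                 n_train = 10)
  expect_equal(up[[1]]$W[1, 1], 1.0 - 0.1 * 0.5) # 0.95
  expect_equal(up[[2]]$W, layers[[2]]$W) # zero gradient: unchanged
})

test_that("with zero data gradient and positive lambda weights purely decay", {
  spec <- toy_dense_spec()
  p <- init_params(spec, 4)
  zero_grads <- lapply(p$layers, function(l) {
    list(W = 0 * l$W, b = 0 * l$b)
  })
  norms0 <- vapply(p$layers, function(l) sum(l$W^2), numeric(1))
  up <- pupilgrid:::apply_update(p$layers, zero_grads, eta = 0.5,
                                 lambda = 0.1, n_train = 10)
  norms1 <- vapply(up, function(l) sum(l$W^2), numeric(1))
  expect_true(all(norms1 < norms0))
  up2 <- pupilgrid:::apply_update(up, zero_grads, 0.5, 0.1, 10)
  norms2 <- vapply(up2, function(l) sum(l$W^2), numeric(1))
  expect_true(all(norms2 < norms1))
})

test_that("one small-step SGD move lowers the mini-batch loss", {
  ds <- generate_dataset(20, "easy", 20, 15, seed = 6)
  p <- init_params(lowres_spec(), 6)
  targets <- coord_to_class(ds$cx, ds$cy, 20, 15)
  loss_of <- function(params) {
    pupilgrid:::.nn_batch_grad_cpp(unclass(params$spec), params$layers,
                                   ds$image, targets, FALSE)$loss
  }
  before <- loss_of(p)
  p2 <- sgd_step(p, ds$image, targets, eta = 0.05, lambda = 0,
                 n_train = 20)
  expect_lt(loss_of(p2), before)
  expect_error(sgd_step(p, list(), integer(0), 0.1, 0, 20),
               class = "pupilgrid_count_error")
})

test_that("training is deterministic and runs the full schedule", {
  ds <- generate_dataset(60, "easy", 20, 15, seed = 8)
  cfg <- train_config(schedule = data.frame(lr = c(0.1, 0.01),
                                            epochs = c(2L, 1L)),
                      seed = 8)
  f1 <- train_network(lowres_spec(), ds, "cell", cfg)
  f2 <- train_network(lowres_spec(), ds, "cell", cfg)
  expect_identical(f1$params$layers, f2$params$layers)
  expect_identical(f1$history, f2$history)
  expect_identical(nrow(f1$history), 3L)
  expect_identical(f1$history$lr, c(0.1, 0.1, 0.01))
})

test_that("the reference schedule totals 38 epochs", {
  expect_identical(sum(train_config()$schedule$epochs), 38L)
})

test_that("an epoch of SGD does not worsen the initial cost", {
  # property check over several seeds: cost after one epoch at most the
  # cost at initialization
  ok <- vapply(1:5, function(seed) {
    ds <- generate_dataset(200, "easy", 20, 15, seed = seed)
    sp <- split_dataset(ds, c(0.8, 0.1, 0.1), seed)
    tgt <- coord_to_class(sp$train$cx, sp$train$cy, 20, 15)
    p0 <- init_params(lowres_spec(), seed)
    c0 <- pupilgrid:::.nn_batch_grad_cpp(unclass(p0$spec), p0$layers,
                                         sp$train$image, tgt, FALSE)$loss
    cfg <- train_config(schedule = data.frame(lr = 0.1, epochs = 1L),
                        seed = seed)
    fit <- train_network(lowres_spec(), sp, "cell", cfg)
    c1 <- pupilgrid:::.nn_batch_grad_cpp(unclass(p0$spec),
                                         fit$params$layers,
                                         sp$train$image, tgt, FALSE)$loss
    c1 <= c0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("early stopping returns the best-validation parameters", {
  ds <- generate_dataset(120, "easy", 20, 15, seed = 12)
  cfg <- train_config(schedule = data.frame(lr = 0.1, epochs = 6L),
                      seed = 12, patience = 2)
  fit <- train_network(lowres_spec(), ds, "cell", cfg)
  expect_lte(nrow(fit$history), 6L)
  # returned parameters must reproduce the best recorded val accuracy
  sp <- split_dataset(ds, cfg$split, cfg$seed)
  tgt <- coord_to_class(sp$val$cx, sp$val$cy, 20, 15)
  acc <- 100 * mean(pupilgrid:::predict_classes(fit$params,
                                                sp$val$image) == tgt)
  expect_equal(acc, max(fit$history$val_accuracy))
})
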