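test_that("pixel error is the Euclidean distance", {
  expect_equal(pixel_error(c(cx = 0, cy = 0), c(cx = 3, cy = 4)), 5)
  expect_equal(pixel_error(c(cx = 7, cy = 9), c(cx = 7, cy = 9)), 0)
  expect_equal(pixel_error(c(cx = 10, cy = 20), c(cx = 13, cy = 24)), 5)
  # vectorized over data frames
  a <- tibble::tibble(cx = c(0, 1), cy = c(0, 1))
  b <- tibble::tibble(cx = c(3, 1), cy = c(4, 2))
  expect_equal(pixel_error(a, b), c(5, 1))
})

test_that("detection rate is an inclusive percentage", {
  expect_equal(detection_rate(c(1, 2, 3, 10), 5), 75)
  expect_equal(detection_rate(rep(0, 7), 0), 100)
  expect_equal(detection_rate(5.0, 5), 100) # boundary is <=
  expect_equal(detection_rate(5.0001, 5), 0)
  expect_error(detection_rate(numeric(0), 5),
               class = "pupilgrid_count_error")
})

test_that("detection rate matches brute force and is monotone in k", {
  set.seed(31)
  for (i in 1:50) {
    d <- runif(sample(5:60, 1), 0, 12)
    ks <- sort(runif(5, 0, 12))
    for (k in ks) {
      brute <- 100 * sum(vapply(d, function(x) x <= k, logical(1))) /
        length(d)
      expect_equal(detection_rate(d, k), brute)
    }
    rates <- vapply(0:12, function(k) detection_rate(d, k), numeric(1))
    expect_true(all(diff(rates) >= 0))
    expect_equal(detection_rate(d, Inf), 100)
  }
})

test_that("sigma is the population standard deviation", {
  expect_equal(sigma_px(c(0, 0, 0)), 0)
  expect_equal(sigma_px(c(2, 2, 4, 4)), 1)
  # Monte-Carlo: half-normal with scale 2 has sd = 2 * sqrt(1 - 2/pi)
  set.seed(5)
  d <- abs(rnorm(10000, 0, 2))
  expect_lt(abs(sigma_px(d) - 2 * sqrt(1 - 2 / pi)) /
              (2 * sqrt(1 - 2 / pi)), 0.03)
})

test_that("evaluation reports are internally consistent", {
  set.seed(41)
  d <- c(runif(30, 0, 4), runif(10, 8, 15))
  rep <- pupilgrid:::new_eval_report(d, "synthetic")
  expect_equal(rep$dr5, detection_rate(d, 5))
  expect_equal(rep$dr5, rep$drk$rate[rep$drk$k == 5])
  expect_equal(rep$sigma, sigma_px(d))
  expect_identical(rep$n_images, 40L)
  expect_identical(rep$lost_frames, sum(d > 10))
  expect_true(all(diff(rep$drk$rate) >= 0))
  g <- glance(rep)
  expect_equal(g$dr5, rep$dr5)
  expect_identical(tidy(rep), rep$drk)
})

test_that("a perfect detector scores DR5 = 100 and sigma = 0", {
  ds <- generate_dataset(12, "easy", 20, 15, seed = 14)
  # oracle detector: softmax bias one-hot at the true cell of image 1 is
  # not possible per-image, so instead evaluate with predictions == truth
  d <- pixel_error(ds[, c("cx", "cy")], ds[, c("cx", "cy")])
  rep <- pupilgrid:::new_eval_report(d, "oracle")
  expect_equal(rep$dr5, 100)
  expect_equal(rep$sigma, 0)
  expect_identical(rep$lost_frames, 0L)
})

test_that("evaluate_detector fills the report from model predictions", {
  ds <- generate_dataset(40, "easy", 20, 15, seed = 15)
  cfg <- train_config(schedule = data.frame(lr = 0.1, epochs = 2L),
                      seed = 15)
  fit <- train_network(lowres_spec(), ds, "cell", cfg)
  rep <- evaluate_detector(lowres_detector(fit), ds)
  expect_identical(rep$n_images, 40L)
  # dr5 must equal an independent recomputation from raw distances
  expect_equal(rep$dr5, detection_rate(rep$distances, 5))
  pred <- predict_centers(lowres_detector(fit), ds$image)
  expect_equal(rep$distances,
               pixel_error(ds[, c("cx", "cy")], pred))
})

test_that("pooled reports recompute from concatenated distances", {
  d1 <- runif(10, 0, 8)
  d2 <- runif(30, 0, 12)
  r1 <- pupilgrid:::new_eval_report(d1, "a")
  r2 <- pupilgrid:::new_eval_report(d2, "b")
  pooled <- pooled_report(list(r1, r2))
  expect_identical(pooled$n_images, 40L)
  expect_equal(pooled$dr5, detection_rate(c(d1, d2), 5))
  expect_equal(pooled$sigma, sigma_px(c(d1, d2)))
  expect_true(all(diff(pooled$drk$rate) >= 0))
  # pooling a report with itself keeps all the rates
  self <- pooled_report(list(r1, r1))
  expect_equal(self$drk$rate, r1$drk$rate)
  expect_error(pooled_report(list()), class = "pupilgrid_count_error")
})

test_that("temporal smoothing rejects outliers against the window median", {
  centers <- tibble::tibble(cx = c(10, 10, 30), cy = c(10, 10, 30))
  sm <- temporal_smooth(centers, window = 3, outlier_threshold = 5)
  expect_identical(sm$cx[2], 10L)
  expect_identical(sm$cy[2], 10L)
  # window 1 is the identity
  id <- temporal_smooth(centers, window = 1, outlier_threshold = 5)
  expect_identical(id$cx, as.integer(centers$cx))
  # constant sequences are untouched
  const <- tibble::tibble(cx = rep(7L, 9), cy = rep(3L, 9))
  expect_identical(temporal_smooth(const, 5, 2), const)
  expect_error(temporal_smooth(centers, window = 2),
               class = "pupilgrid_config_error")
})

test_that("smoothing keeps coordinates within the hull of the track", {
  set.seed(77)
  centers <- tibble::tibble(cx = sample(0:319, 50, TRUE),
                            cy = sample(0:239, 50, TRUE))
  sm <- temporal_smooth(centers, 5, 10)
  expect_true(all(sm$cx >= min(centers$cx) & sm$cx <= max(centers$cx)))
  expect_true(all(sm$cy >= min(centers$cy) & sm$cy <= max(centers$cy)))
})
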