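test_that("mse_loss and mae are exact against hand arithmetic", {
  expect_equal(mse_loss(c(10, 20), c(13, 16)), 12.5)
  expect_equal(mae(c(12, 24), c(10, 30)), 4)
  y <- c(1.5, -2, 7)
  expect_equal(mse_loss(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_error(mse_loss(1:3, 1:2), "length mismatch")
  expect_error(mae(1:2, 1:3), "length mismatch")
})

test_that("metrics match independent oracles to 1e-10 and satisfy Jensen", {
  set.seed(50)
  for (i in 1:20) {
    n <- sample(2:200, 1)
    y <- rnorm(n, 100, 40); g <- rnorm(n, 100, 40)
    r <- y - g
    expect_equal(mse_loss(y, g), drop(crossprod(r)) / n, tolerance = 1e-10)
    expect_equal(mae(y, g), sum(abs(r)) / n, tolerance = 1e-10)
  }
  # homogeneity: scaling residuals by c multiplies MSE by c^2
  y <- rnorm(50); g <- rnorm(50)
  expect_equal(mse_loss(g + 3 * (y - g), g), 9 * mse_loss(y, g),
               tolerance = 1e-10)
  # MAE <= sqrt(MSE) on 1000 random vectors
  for (i in 1:1000) {
    n <- sample(1:30, 1)
    y <- rnorm(n, sd = 10); g <- rnorm(n, sd = 10)
    expect_lte(mae(y, g), sqrt(mse_loss(y, g)) + 1e-12)
  }
})

test_that("augmentation is seeded, ordered, and collapses to plain resize", {
  set.seed(60)
  img <- matrix(runif(48 * 40), 48, 40)
  cfg_off <- train_config(input_size = c(32, 32), augment = FALSE)
  plain <- augment(img, seed = 5, cfg = cfg_off)
  expect_equal(dim(plain), c(32, 32))
  expect_identical(plain, resize_bilinear(img, 32, 32))
  # constant image maps to a constant under the resize-only path
  expect_true(all(abs(augment(matrix(0.3, 20, 20), 1, cfg_off) - 0.3) < 1e-12))
  # same seed -> bit-identical output
  cfg_on <- train_config(input_size = c(32, 32), augment = TRUE)
  a1 <- augment(img, seed = 9, cfg = cfg_on)
  a2 <- augment(img, seed = 9, cfg = cfg_on)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment(img, seed = 10, cfg = cfg_on)))
  # all magnitudes zeroed: augmented path equals the resize-only path
  cfg_zero <- train_config(input_size = c(32, 32), augment = TRUE,
                           angle_max = 0, contrast_range = c(1, 1),
                           brightness_max = 0, resize_jitter = 0)
  expect_equal(augment(img, 3, cfg_zero), plain, tolerance = 1e-6)
})

test_that("augmentation does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(augment(matrix(0.5, 8, 8), 1,
                    train_config(input_size = c(8, 8), augment = TRUE)))
  expect_identical(runif(1), before)
})

test_that("split_indices partitions reproducibly into 80/10/10", {
  s1 <- split_indices(100, seed = 4)
  s2 <- split_indices(100, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1$train, 80)
  expect_length(s1$val, 10)
  expect_length(s1$test, 10)
  expect_identical(sort(c(s1$train, s1$val, s1$test)), 1:100)
})

test_that("training runs, logs history, and respects degenerate settings", {
  samples <- tiny_image_samples(4)
  set.seed(1)
  net <- build_region_extractor(c(8, 8), use_cbam = FALSE, channels = 4)
  cfg <- train_config(epochs = 1, batch_size = 2, input_size = c(8, 8),
                      seed = 1)
  tr <- train_model(net, samples, cfg)
  expect_equal(nrow(tr$history), 1)
  expect_true(all(c("epoch", "train_mse", "train_mae") %in% names(tr$history)))
  # zero learning rate leaves every parameter untouched
  cfg0 <- train_config(learning_rate = 0, epochs = 2, batch_size = 2,
                       input_size = c(8, 8), seed = 1)
  set.seed(1)
  net2 <- build_region_extractor(c(8, 8), use_cbam = FALSE, channels = 4)
  tr0 <- train_model(net2, samples, cfg0)
  expect_identical(osteoage:::net_params(tr0$model),
                   osteoage:::net_params(net2))
  expect_error(train_model(net, list(), cfg), "empty")
})

test_that("loss decreases on a linearly solvable problem", {
  # images whose mean encodes the target: trivially solvable by the net
  set.seed(2)
  samples <- lapply(1:24, function(i) {
    v <- runif(1)
    list(image = matrix(v + rnorm(64, sd = 0.01), 8, 8),
         age_months = 50 + 100 * v)
  })
  set.seed(2)
  net <- build_region_extractor(c(8, 8), use_cbam = FALSE, channels = 4)
  cfg <- train_config(learning_rate = 5e-3, epochs = 10, batch_size = 8,
                      input_size = c(8, 8), seed = 2)
  tr <- train_model(net, samples, cfg)
  expect_lt(tr$history$train_mse[10], tr$history$train_mse[1])
})

test_that("non-finite losses raise a structured error", {
  samples <- tiny_image_samples(4)
  samples[[2]]$age_months <- NaN
  set.seed(3)
  net <- build_region_extractor(c(8, 8), use_cbam = FALSE, channels = 4)
  cfg <- train_config(epochs = 2, batch_size = 4, input_size = c(8, 8),
                      seed = 3)
  expect_error(train_model(net, samples, cfg), "non-finite")
})

test_that("seeded training reproduces its history", {
  samples <- tiny_image_samples(6)
  mk <- function() {
    set.seed(11)
    net <- build_region_extractor(c(8, 8), use_cbam = FALSE, channels = 4)
    train_model(net, samples,
                train_config(epochs = 2, batch_size = 3,
                             input_size = c(8, 8), seed = 11))
  }
  expect_identical(mk()$history, mk()$history)
})

test_that("evaluate_model reports per-sample errors and ignores ordering", {
  samples <- tiny_crop_samples(8)
  set.seed(12)
  m <- build_model(branch_config(input_size = c(16, 16)),
                   branch_config(input_size = c(16, 16)))
  # constant predictor: zeroed head with a bias
  m$head2$params$W[] <- 0
  m$head2$params$b <- 110
  ev <- evaluate_model(m, samples)
  y <- vapply(samples, `[[`, 0, "age_months")
  expect_equal(nrow(ev$per_sample), 8)
  expect_equal(ev$mae, mean(abs(y - 110)), tolerance = 1e-10)
  perm <- sample(8)
  ev2 <- evaluate_model(m, samples[perm])
  expect_equal(ev2$mae, ev$mae, tolerance = 1e-12)
  expect_equal(ev2$per_sample[order(ev2$per_sample$id), ],
               ev$per_sample[order(ev$per_sample$id), ],
               ignore_attr = TRUE)
  # a perfect oracle scores zero: predict each sample's own label
  ps <- ev$per_sample
  expect_equal(mae(ps$true_months, ps$true_months), 0)
})

test_that("training histories serialize as line-delimited JSON", {
  h <- data.frame(epoch = 1:3, train_mse = c(9, 4, 1),
                  train_mae = c(3, 2, 1))
  tf <- tempfile(fileext = ".ndjson")
  write_train_log(h, tf, seed = 12)
  lines <- readLines(tf)
  expect_length(lines, 3)
  recs <- lapply(lines, jsonlite::fromJSON)
  expect_equal(vapply(recs, `[[`, 0, "epoch"), 1:3, ignore_attr = TRUE)
  expect_equal(recs[[2]]$train_mae, 2)
  expect_equal(recs[[1]]$seed, 12)
  expect_true(nzchar(recs[[1]]$package_version))
})

test_that("fit_bone_age returns a working classed model object", {
  samples <- tiny_crop_samples(30)
  cfg <- train_config(learning_rate = 3e-3, epochs = 2, batch_size = 8,
                      input_size = c(16, 16), seed = 5)
  fit <- fit_bone_age(samples, use_gender = TRUE, use_cbam = FALSE,
                      crop_size = c(16, 16), cfg = cfg)
  expect_s3_class(fit, "bone_age_model")
  expect_named(coef(fit), c("alpha_D", "alpha_G"))
  expect_length(predict(fit, samples[1:3]), 3)
  expect_length(residuals(fit), length(fit$split$test))
  expect_output(print(fit), "test MAE")
  expect_output(summary(fit), "fusion weights")
  expect_equal(nrow(fit$evaluation$per_sample), length(fit$split$test))
})
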