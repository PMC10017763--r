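test_that("exchange_and_concat swaps whole vectors then concatenates", {
  ex <- exchange_and_concat(c(1, 2), 3)
  expect_equal(ex$path_a, c(3, 1, 2))
  expect_equal(ex$path_b, c(1, 2, 3))
  # dimension contract
  set.seed(1)
  fa <- rnorm(5); fb <- rnorm(3)
  ex2 <- exchange_and_concat(fa, fb)
  expect_length(ex2$path_a, 8)
  expect_length(ex2$path_b, 8)
  # the swap is an involution: swapping the arguments restores routing
  ex3 <- exchange_and_concat(fb, fa)
  expect_equal(ex3$path_a, ex2$path_b)
  expect_equal(ex3$path_b, ex2$path_a)
})

test_that("fuse_gender computes the weighted sum and checks dimensions", {
  x <- c(1, 1); g <- c(2, 0)
  expect_equal(fuse_gender(x, g, 1, 0), x)
  expect_equal(fuse_gender(x, g, 0, 0), c(0, 0))
  expect_equal(fuse_gender(x, g, 0.5, 2), c(4.5, 0.5))
  expect_error(fuse_gender(c(1, 2), c(1, 2, 3), 1, 1), "dimension mismatch")
})

test_that("build_model validates backbones and reproduces the ablation arms", {
  expect_error(branch_config("vgg"), "registered backbones")
  expect_error(osteoage:::build_branch(branch_config("xception"), FALSE),
               "not bundled")
  cfgs <- expand.grid(gender = c(FALSE, TRUE), cbam = c(FALSE, TRUE))
  counts <- vapply(seq_len(nrow(cfgs)), function(i) {
    set.seed(10)
    m <- build_model(branch_config(input_size = c(16, 16)),
                     branch_config(input_size = c(16, 16)),
                     use_gender = cfgs$gender[i], use_cbam = cfgs$cbam[i])
    n_params(m)
  }, numeric(1))
  expect_length(unique(counts), 4)              # four structurally distinct arms
  expect_true(counts[1] < counts[2])            # gender adds parameters
  expect_true(counts[1] < counts[3])            # cbam adds parameters
})

test_that("forward pass is deterministic, shape-safe, and validates crops", {
  set.seed(20)
  m <- build_model(branch_config(input_size = c(16, 16)),
                   branch_config(input_size = c(16, 16)))
  ca <- matrix(runif(256), 16, 16); cb <- matrix(runif(256), 16, 16)
  p1 <- predict_age(m, ca, cb, TRUE)
  expect_identical(p1, predict_age(m, ca, cb, TRUE))
  expect_error(predict_age(m, matrix(0, 8, 8), cb, TRUE), "expects 16x16")
  # wide backbone pairs also run
  set.seed(21)
  mw <- build_model(branch_config("small_cnn_wide", c(16, 16)),
                    branch_config(input_size = c(16, 16)))
  expect_true(is.finite(predict_age(mw, ca, cb, FALSE)))
  # a 64 x 64 small_cnn pair runs a forward pass
  set.seed(22)
  m64 <- build_model(branch_config(input_size = c(64, 64)),
                     branch_config(input_size = c(64, 64)))
  expect_true(is.finite(predict_age(m64, matrix(runif(4096), 64, 64),
                                    matrix(runif(4096), 64, 64), TRUE)))
})

test_that("a zeroed head predicts exactly its bias", {
  set.seed(23)
  m <- build_model(branch_config(input_size = c(16, 16)),
                   branch_config(input_size = c(16, 16)))
  m$head2$params$W[] <- 0
  m$head2$params$b <- 4.2
  expect_equal(predict_age(m, matrix(0, 16, 16), matrix(0, 16, 16), FALSE), 4.2)
})

test_that("gradients flow to the fusion weights on a nondegenerate batch", {
  set.seed(24)
  m <- build_model(branch_config(input_size = c(16, 16)),
                   branch_config(input_size = c(16, 16)))
  fw <- osteoage:::fusion_forward(m, matrix(runif(256), 16, 16),
                                  matrix(runif(256), 16, 16), 1, keep = TRUE)
  gr <- osteoage:::fusion_backward(m, fw$cache, 1)
  expect_true(abs(gr$alpha$alpha_d) > 0)
  expect_true(abs(gr$alpha$alpha_g) > 0)
  expect_true(any(gr$gender$We != 0))
})

test_that("fusion backward matches finite differences on scalar weights", {
  set.seed(25)
  m <- build_model(branch_config(input_size = c(8, 8), feature_dim = 4),
                   branch_config(input_size = c(8, 8), feature_dim = 4),
                   p_dim = 6, head_hidden = 5)
  ca <- matrix(runif(64), 8, 8); cb <- matrix(runif(64), 8, 8)
  fw <- osteoage:::fusion_forward(m, ca, cb, 1, keep = TRUE)
  gr <- osteoage:::fusion_backward(m, fw$cache, 1)
  eps <- 1e-6
  for (nm in c("alpha_d", "alpha_g")) {
    mp <- m; mp$alpha[[nm]] <- mp$alpha[[nm]] + eps
    mm <- m; mm$alpha[[nm]] <- mm$alpha[[nm]] - eps
    fd <- (osteoage:::fusion_forward(mp, ca, cb, 1)$out -
             osteoage:::fusion_forward(mm, ca, cb, 1)$out) / (2 * eps)
    expect_equal(gr$alpha[[nm]], fd, tolerance = 1e-5)
  }
  # a branch parameter deep in the network
  i <- 3
  mp <- m; mp$branch_a$layers[[1]]$params$W[i] <- mp$branch_a$layers[[1]]$params$W[i] + eps
  mm <- m; mm$branch_a$layers[[1]]$params$W[i] <- mm$branch_a$layers[[1]]$params$W[i] - eps
  fd <- (osteoage:::fusion_forward(mp, ca, cb, 1)$out -
           osteoage:::fusion_forward(mm, ca, cb, 1)$out) / (2 * eps)
  expect_equal(gr$branch_a[[1]]$W[i], fd, tolerance = 1e-4)
})

test_that("the gender pathway is live after training a small fixture", {
  samples <- tiny_crop_samples(16)
  # plant a strong gender effect so the pathway must be used
  samples <- lapply(samples, function(s) {
    s$age_months <- 100 + 40 * s$male
    s
  })
  cfg <- train_config(learning_rate = 5e-3, epochs = 8, batch_size = 8,
                      input_size = c(16, 16), seed = 7)
  set.seed(7)
  m <- build_model(branch_config(input_size = c(16, 16)),
                   branch_config(input_size = c(16, 16)))
  tr <- train_model(m, samples, cfg)
  s <- samples[[1]]
  d <- predict_age(tr$model, s$crop_a, s$crop_b, TRUE) -
    predict_age(tr$model, s$crop_a, s$crop_b, FALSE)
  expect_gt(abs(d), 1)   # flipping the flag moves the prediction
})

test_that("checkpoints round-trip models with their config block", {
  set.seed(30)
  m <- build_model(branch_config(input_size = c(16, 16)),
                   branch_config(input_size = c(16, 16)))
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(m, tf, extra = list(seed = 30))
  m2 <- load_checkpoint(tf)
  cfg <- attr(m2, "config")
  expect_equal(cfg$model_class, "fusion_model")
  expect_equal(cfg$seed, 30)
  expect_match(cfg$coordinates, "0-based")
  ca <- matrix(runif(256), 16, 16); cb <- matrix(runif(256), 16, 16)
  expect_identical(predict_age(m, ca, cb, TRUE), predict_age(m2, ca, cb, TRUE))
})
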