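# Losses, metrics, augmentation and the Adam training loop shared by the
# stage-1 region network and the stage-2 fusion regressor. Targets are
# standardized internally (center/scale from the training labels) and all
# logged metrics are reported back in months.

#' Mean squared error loss
#'
#' `(1/n) * sum((y - g)^2)` over paired vectors of true and predicted ages
#' in months.
#'
#' @param y,g equal-length numeric vectors.
#' @return scalar MSE.
#' @export
mse_loss <- function(y, g) {
  if (length(y) != length(g))
    stop("length mismatch: y has ", length(y), " elements, g has ", length(g))
  stopifnot(length(y) >= 1)
  mean((y - g)^2)
}

#' Mean absolute error
#'
#' `(1/N) * sum(|y - yhat|)`, the standard bone-age-assessment metric, in
#' months.
#'
#' @param y,yhat equal-length numeric vectors.
#' @return scalar MAE.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("length mismatch: y has ", length(y), " elements, yhat has ",
         length(yhat))
  stopifnot(length(y) >= 1)
  mean(abs(y - yhat))
}

#' Training configuration
#'
#' Defaults follow the reference training settings: learning rate 3e-4,
#' 30 epochs, 300 x 300 working resolution; batch size 16 and the
#' augmentation magnitudes are package defaults.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs number of epochs (>= 1).
#' @param batch_size minibatch size.
#' @param input_size `(h, w)` images are resized to before the network.
#' @param seed RNG seed controlling init, shuffling and augmentation.
#' @param augment logical: apply the augmentation pipeline during
#'   training.
#' @param angle_max rotation range (degrees, +/-).
#' @param contrast_range multiplicative contrast range about the image
#'   mean.
#' @param brightness_max additive brightness shift range (+/-, intensity
#'   units).
#' @param resize_jitter fractional resize jitter before the final resize.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 3e-4, epochs = 30L, batch_size = 16L,
                         input_size = c(300L, 300L), seed = 1L,
                         augment = FALSE, angle_max = 15,
                         contrast_range = c(0.8, 1.2), brightness_max = 0.1,
                         resize_jitter = 0.1) {
  stopifnot(learning_rate > 0 || learning_rate == 0, epochs >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), seed = as.integer(seed),
                 augment = augment, angle_max = angle_max,
                 contrast_range = contrast_range,
                 brightness_max = brightness_max,
                 resize_jitter = resize_jitter),
            class = "train_config")
}

#' Seeded image augmentation
#'
#' Applies, in order: resize jitter, rotation within `+/- angle_max`
#' degrees, contrast scaling about the image mean, and a brightness shift,
#' each drawn from a generator seeded with `seed`; the output is resized
#' to `cfg$input_size` and clamped to `[0, 1]`. With all augmentations
#' disabled this reduces to the plain resize.
#'
#' @param image grayscale matrix in `[0,1]`.
#' @param seed integer seed; the same seed reproduces the augmentation
#'   bit-identically.
#' @param cfg a [train_config()].
#' @return augmented matrix of size `cfg$input_size`.
#' @export
augment <- function(image, seed, cfg = train_config()) {
  with_local_seed(seed, {
    out <- image
    if (isTRUE(cfg$augment)) {
      if (cfg$resize_jitter > 0) {
        s <- runif(1, 1 - cfg$resize_jitter, 1 + cfg$resize_jitter)
        out <- resize_bilinear(out, max(2, round(cfg$input_size[1] * s)),
                               max(2, round(cfg$input_size[2] * s)))
      }
      if (cfg$angle_max > 0)
        out <- rotate_image(out, runif(1, -cfg$angle_max, cfg$angle_max))
      out <- resize_bilinear(out, cfg$input_size[1], cfg$input_size[2])
      cs <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
      out <- mean(out) + cs * (out - mean(out))
      out <- out + runif(1, -cfg$brightness_max, cfg$brightness_max)
      clamp01(out)
    } else {
      resize_bilinear(out, cfg$input_size[1], cfg$input_size[2])
    }
  })
}

#' 80/10/10 train/validation/test split
#'
#' Seeded shuffle split used for all synthetic experiments.
#'
#' @param n number of samples.
#' @param seed shuffle seed.
#' @param frac length-3 fractions summing to 1.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, seed = 1L, frac = c(0.8, 0.1, 0.1)) {
  idx <- with_local_seed(seed, sample.int(n))
  n_tr <- floor(frac[1] * n); n_va <- floor(frac[2] * n)
  list(train = sort(idx[seq_len(n_tr)]),
       val = sort(idx[n_tr + seq_len(n_va)]),
       test = sort(idx[(n_tr + n_va + 1):n]))
}

# ---- internal per-sample forward/backward dispatch ---------------------

sample_fwd <- function(model, s, keep = FALSE) {
  if (inherits(model, "fusion_model"))
    fusion_forward(model, s$crop_a, s$crop_b, as.numeric(s$male), keep = keep)
  else
    nn_forward(model, array(s$image, c(dim(s$image), 1L)), keep = keep)
}

sample_bwd <- function(model, cache_or_fw, g) {
  if (inherits(model, "fusion_model")) fusion_backward(model, cache_or_fw$cache, g)
  else nn_backward(model, cache_or_fw$caches, g)$grads
}

model_get_params <- function(model) {
  if (inherits(model, "fusion_model")) fusion_params(model) else net_params(model)
}

model_with_params <- function(model, p) {
  if (inherits(model, "fusion_model")) fusion_set_params(model, p)
  else net_set_params(model, p)
}

model_target <- function(model, center, scale) {
  model$target_center <- center
  model$target_scale <- scale
  model
}

#' Train a model by minimizing mean squared error
#'
#' Runs seeded minibatch Adam on the MSE loss over standardized age
#' targets. Works for both model kinds: a `fusion_model` (samples need
#' `crop_a`, `crop_b`, `male`, `age_months`) and a scalar-output
#' `osteo_net` (samples need `image`, `age_months`). Per-epoch training
#' and validation MSE/MAE (in months) are recorded in the history. Given
#' the same seed the run is reproducible to floating-point identity on the
#' same numerics backend.
#'
#' @param model the untrained model.
#' @param dataset non-empty list of training samples.
#' @param cfg a [train_config()].
#' @param val optional list of validation samples.
#' @param select `"final"` returns the last-epoch parameters;
#'   `"best_val"` (requires `val`) returns the parameters of the epoch
#'   with the lowest validation MAE — the usual guard against late-epoch
#'   optimization noise.
#' @return list with `model` (trained) and `history` (data frame with one
#'   row per epoch; for `"best_val"` also a `best_epoch` element).
#' @export
train_model <- function(model, dataset, cfg = train_config(), val = NULL,
                        select = c("final", "best_val")) {
  select <- match.arg(select)
  if (select == "best_val" && (is.null(val) || !length(val)))
    stop("select = 'best_val' needs a validation set")
  if (length(dataset) == 0) stop("dataset is empty")
  y <- vapply(dataset, `[[`, 0, "age_months")
  center <- mean(y); scale <- max(stats::sd(y), 1e-8)
  model <- model_target(model, center, scale)
  params <- model_get_params(model)
  state <- adam_init(params)
  hist <- data.frame()
  n <- length(dataset)
  best <- list(mae = Inf, params = NULL, epoch = NA_integer_)
  for (ep in seq_len(cfg$epochs)) {
    # derived seeds computed in double and wrapped below 2^31 - 1
    ord <- with_local_seed((as.numeric(cfg$seed) * 1000 + ep) %% 2147483647,
                           sample.int(n))
    preds_std <- numeric(n)
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      bi <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      acc <- NULL
      for (i in bi) {
        s <- dataset[[i]]
        if (isTRUE(cfg$augment)) {
          aseed <- (as.numeric(cfg$seed) * 100000 + ep * 1000 + i) %% 2147483647
          if (inherits(model, "fusion_model")) {
            s$crop_a <- augment(s$crop_a, aseed, cfg)
            s$crop_b <- augment(s$crop_b, aseed + 500L, cfg)
          } else {
            s$image <- augment(s$image, aseed, cfg)
          }
        }
        fw <- sample_fwd(model, s, keep = TRUE)
        pred <- fw$out
        preds_std[i] <- pred
        resid <- 2 * (pred - (s$age_months - center) / scale) / length(bi)
        acc <- grads_add(acc, sample_bwd(model, fw, resid))
      }
      up <- adam_update(params, acc, state, cfg$learning_rate)
      params <- up$params; state <- up$state
      model <- model_with_params(model, params)
    }
    pred_m <- preds_std * scale + center
    if (!all(is.finite(pred_m)))
      stop("loss became non-finite at epoch ", ep,
           "; lower the learning rate or check the inputs")
    row <- data.frame(epoch = ep, train_mse = mse_loss(y, pred_m),
                      train_mae = mae(y, pred_m))
    if (!is.null(val) && length(val)) {
      ev <- evaluate_model(model, val)
      row$val_mse <- mse_loss(ev$per_sample$true_months,
                              ev$per_sample$pred_months)
      row$val_mae <- ev$mae
      if (ev$mae < best$mae)
        best <- list(mae = ev$mae, params = params, epoch = ep)
    }
    hist <- rbind(hist, row)
  }
  out <- list(model = model, history = hist)
  if (select == "best_val") {
    out$model <- model_with_params(model, best$params)
    out$best_epoch <- best$epoch
  }
  out
}

#' Evaluate a model on a dataset
#'
#' @param model trained `fusion_model` or `osteo_net`.
#' @param dataset non-empty sample list (see [train_model()]).
#' @return list with `mae` (months) and `per_sample`, a data frame with
#'   columns `id`, `true_months`, `pred_months`, `abs_err` (one row per
#'   sample, suitable for a true-vs-predicted scatter plot).
#' @export
evaluate_model <- function(model, dataset) {
  stopifnot(length(dataset) >= 1)
  pred <- vapply(dataset, function(s)
    sample_fwd(model, s)$out * model$target_scale + model$target_center,
    numeric(1))
  truev <- vapply(dataset, `[[`, 0, "age_months")
  ids <- vapply(seq_along(dataset), function(i) {
    id <- dataset[[i]]$id
    if (is.null(id)) sprintf("sample%04d", i) else id
  }, "")
  ps <- data.frame(id = ids, true_months = truev, pred_months = pred,
                   abs_err = abs(truev - pred))
  list(mae = mae(truev, pred), per_sample = ps)
}

#' Write a training history as line-delimited JSON
#'
#' One JSON object per epoch (the columns of the history data frame),
#' each stamped with the package version and, when given, the seed.
#'
#' @param history history data frame from [train_model()].
#' @param path output path.
#' @param seed optional seed to embed in every record.
#' @export
write_train_log <- function(history, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(packageVersion("osteoage"))
  for (i in seq_len(nrow(history))) {
    rec <- as.list(history[i, ])
    rec$package_version <- ver
    if (!is.null(seed)) rec$seed <- seed
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Build the stage-1 region-extraction network
#'
#' A small CNN age regressor over whole radiographs, optionally with a
#' CBAM block after the first convolution stage; its Grad-CAM maps drive
#' [extract_cascade()].
#'
#' @param input_size `(h, w)` image size.
#' @param use_cbam insert a CBAM block (default `TRUE`).
#' @param channels first-stage channel count.
#' @return scalar-output `osteo_net`.
#' @export
build_region_extractor <- function(input_size = c(64L, 64L), use_cbam = TRUE,
                                   channels = 8L) {
  layers <- list(layer_conv(1, channels, 3), layer_relu(), layer_maxpool2())
  if (use_cbam) layers <- c(layers, list(layer_cbam(channels, r = 4L)))
  layers <- c(layers, list(layer_conv(channels, 2L * channels, 3), layer_relu(),
                           layer_maxpool2(), layer_gap(),
                           layer_dense(2L * channels, 1L)))
  do.call(nn_sequential, c(layers, list(input_size = c(input_size, 1L))))
}
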