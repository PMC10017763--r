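# User-facing modelling interface: one fitting function returning a
# classed object with the usual accessor methods.

#' Fit the two-branch bone age model
#'
#' Splits the samples 80/10/10 (seeded shuffle), builds the two-branch
#' fusion regressor, trains it with minibatch Adam on the MSE loss, and
#' evaluates on the held-out test fold. Each sample must carry `crop_a`
#' (carpal crop), `crop_b` (metacarpus/phalanx crop), `male` and
#' `age_months`; crops are resized to `crop_size` with bilinear
#' interpolation if needed.
#'
#' @param samples list of samples as above.
#' @param use_gender,use_cbam ablation switches (both default `TRUE`, the
#'   full model).
#' @param backbone_a,backbone_b backbone names (see [branch_config()]).
#' @param crop_size `(h, w)` branch input size.
#' @param feature_dim branch feature dimension.
#' @param d_g gender embedding dimension.
#' @param cfg a [train_config()]; `cfg$seed` also seeds the split and the
#'   weight initialization.
#' @param split optional precomputed [split_indices()] list.
#' @return an object of class `bone_age_model` with components `model`,
#'   `history`, `evaluation` (test-fold [evaluate_model()] output),
#'   `split`, `cfg` and `call`.
#' @export
fit_bone_age <- function(samples, use_gender = TRUE, use_cbam = TRUE,
                         backbone_a = "small_cnn", backbone_b = "small_cnn",
                         crop_size = c(32L, 32L), feature_dim = 16L,
                         d_g = 32L, cfg = train_config(), split = NULL) {
  stopifnot(length(samples) >= 5)
  samples <- lapply(samples, function(s) {
    if (!all(dim(s$crop_a) == crop_size))
      s$crop_a <- resize_bilinear(s$crop_a, crop_size[1], crop_size[2])
    if (!all(dim(s$crop_b) == crop_size))
      s$crop_b <- resize_bilinear(s$crop_b, crop_size[1], crop_size[2])
    s
  })
  if (is.null(split)) split <- split_indices(length(samples), seed = cfg$seed)
  model <- with_local_seed(cfg$seed, build_model(
    cfg_a = branch_config(backbone_a, crop_size, feature_dim),
    cfg_b = branch_config(backbone_b, crop_size, feature_dim),
    gender = gender_encoder(d_g),
    use_cbam = use_cbam, use_gender = use_gender))
  tr <- train_model(model, samples[split$train], cfg,
                    val = samples[split$val],
                    select = if (length(split$val)) "best_val" else "final")
  ev <- evaluate_model(tr$model, samples[split$test])
  structure(list(model = tr$model, history = tr$history, evaluation = ev,
                 best_epoch = tr$best_epoch, split = split, cfg = cfg,
                 call = match.call()),
            class = "bone_age_model")
}

#' @export
print.bone_age_model <- function(x, ...) {
  cat("Two-branch bone age model\n")
  cat("  gender pathway:", x$model$cfg$use_gender,
      " cbam:", x$model$cfg$use_cbam, "\n")
  cat("  samples: train", length(x$split$train), "/ val", length(x$split$val),
      "/ test", length(x$split$test), "\n")
  cat(sprintf("  test MAE: %.2f months\n", x$evaluation$mae))
  invisible(x)
}

#' @export
summary.bone_age_model <- function(object, ...) {
  h <- object$history
  cat("Two-branch bone age model (", n_params(object$model), " parameters )\n")
  print(object)
  if ("val_mae" %in% names(h))
    cat(sprintf("  final epoch: train MAE %.2f / val MAE %.2f months\n",
                h$train_mae[nrow(h)], h$val_mae[nrow(h)]))
  if (object$model$cfg$use_gender)
    cat(sprintf("  fusion weights: alpha_D = %.4f, alpha_G = %.4f\n",
                object$model$alpha$alpha_d, object$model$alpha$alpha_g))
  invisible(object)
}

#' @export
coef.bone_age_model <- function(object, ...) {
  if (object$model$cfg$use_gender)
    c(alpha_D = object$model$alpha$alpha_d,
      alpha_G = object$model$alpha$alpha_g)
  else c(alpha_D = 1)
}

#' @export
predict.bone_age_model <- function(object, newdata, ...) {
  cs <- object$model$cfg$cfg_a$input_size
  vapply(newdata, function(s) {
    ca <- if (all(dim(s$crop_a) == cs)) s$crop_a
          else resize_bilinear(s$crop_a, cs[1], cs[2])
    cb <- if (all(dim(s$crop_b) == cs)) s$crop_b
          else resize_bilinear(s$crop_b, cs[1], cs[2])
    predict_age(object$model, ca, cb, s$male)
  }, numeric(1))
}

#' @export
residuals.bone_age_model <- function(object, ...) {
  object$evaluation$per_sample$pred_months -
    object$evaluation$per_sample$true_months
}

#' @export
plot.bone_age_model <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_mae, type = "l", xlab = "epoch",
                 ylab = "MAE (months)", ylim = range(c(h$train_mae, h$val_mae),
                                                     na.rm = TRUE), ...)
  if ("val_mae" %in% names(h))
    graphics::lines(h$epoch, h$val_mae, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Run the four-arm ablation
#'
#' Fits the stage-2 model under all four combinations of the gender
#' pathway and CBAM switches on the same samples and split, mirroring the
#' structure of the reference ablation (with/without gender, with/without
#' attention).
#'
#' @inheritParams fit_bone_age
#' @return data frame with columns `gender`, `cbam`, `mae`,
#'   `n_parameters` (one row per arm).
#' @export
run_ablation <- function(samples, cfg = train_config(), ...) {
  arms <- expand.grid(gender = c(FALSE, TRUE), cbam = c(FALSE, TRUE))
  split <- split_indices(length(samples), seed = cfg$seed)
  res <- lapply(seq_len(nrow(arms)), function(i) {
    fit <- fit_bone_age(samples, use_gender = arms$gender[i],
                        use_cbam = arms$cbam[i], cfg = cfg, split = split, ...)
    data.frame(gender = arms$gender[i], cbam = arms$cbam[i],
               mae = fit$evaluation$mae, n_parameters = n_params(fit$model))
  })
  do.call(rbind, res)
}
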