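# Shared fixtures. The expensive end-to-end pipeline fixture is built
# lazily once and reused across acceptance blocks.

.fixture_env <- new.env(parent = emptyenv())

# dataset -> cascade (toy saliency) -> fixed-scale crops
pipeline_samples <- function(ds) {
  toy <- toy_saliency_model(attr(ds, "params"))
  lapply(ds, function(s) {
    res <- extract_cascade(toy, s$image)
    stopifnot(length(res$boxes) == 2)
    list(id = s$id,
         crop_a = crop_fixed(s$image, res$boxes[[1]], c(32L, 32L)),
         crop_b = crop_fixed(s$image, res$boxes[[2]], c(32L, 32L)),
         male = s$male, age_months = s$age_months)
  })
}

e2e_cfg <- function(seed) {
  train_config(learning_rate = 2e-3, epochs = 40L, batch_size = 16L,
               input_size = c(32L, 32L), seed = seed)
}

get_e2e_fixture <- function() {
  if (!is.null(.fixture_env$e2e)) return(.fixture_env$e2e)
  seed <- 1L
  p <- synth_params(n_samples = 500L, seed = seed)
  ds <- generate_dataset(p)
  samples <- pipeline_samples(ds)
  cfg <- e2e_cfg(seed)
  fit_g <- fit_bone_age(samples, use_gender = TRUE, use_cbam = TRUE, cfg = cfg)
  fit_n <- fit_bone_age(samples, use_gender = FALSE, use_cbam = TRUE, cfg = cfg)
  y <- vapply(samples, `[[`, 0, "age_months")
  baseline <- mae(y[fit_g$split$test],
                  rep(mean(y[fit_g$split$train]), length(fit_g$split$test)))
  # large independently simulated evaluation cohort: measures the
  # generalization gap between arms with far less fold noise than the
  # 50-sample test split
  p_eval <- synth_params(n_samples = 300L, seed = seed + 50000L)
  eval_samples <- pipeline_samples(generate_dataset(p_eval))
  .fixture_env$e2e <- list(p = p, ds = ds, samples = samples, cfg = cfg,
                           fit_gender = fit_g, fit_no_gender = fit_n,
                           baseline = baseline, eval_samples = eval_samples)
  .fixture_env$e2e
}

tiny_image_samples <- function(n, size = 8L, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(id = sprintf("t%02d", i),
         image = matrix(runif(size * size), size, size),
         age_months = runif(1, 12, 216), male = i %% 2 == 0)
  })
}

tiny_crop_samples <- function(n, size = 16L, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(id = sprintf("c%02d", i),
         crop_a = matrix(runif(size * size), size, size),
         crop_b = matrix(runif(size * size), size, size),
         age_months = runif(1, 12, 216), male = i %% 2 == 0)
  })
}
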