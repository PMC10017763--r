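# osteoage

Annotation-free, two-stage bone age assessment from hand radiographs.

Pediatric bone age is read from a left-hand radiograph by examining a
handful of anatomically informative regions — the carpal bones and the
metacarpus & phalanx bones above all. Deep-learning pipelines either feed
the whole radiograph to one network (ignoring that clinical prior) or
require manually drawn region boxes (slow, subjective). `osteoage`
implements the annotation-free middle road for R users:

1. **Cascaded critical-region discovery.** A CBAM-augmented convolutional
   age regressor is interrogated with Grad-CAM. The heat map's *peak
   attention area* — the 8-connected component above half the maximum,
   around the argmax — becomes the first region box; the box is cropped,
   masked with a black rectangle, and saliency is re-run so attention
   shifts to the second region. Formally, channel and spatial attention
   are

   `Mc(F) = sigma( MLP(AvgPool(F)) + MLP(MaxPool(F)) )`,
   `Ms(F) = sigma( f7x7([AvgPool(F); MaxPool(F)]) )`,

   applied sequentially, and the Grad-CAM map weights each channel of a
   chosen layer by the spatial mean of `d(age)/d(activation)`.

2. **Two-branch fusion regression.** Branch CNNs embed the two crops;
   their feature vectors are exchanged as a whole and concatenated (each
   path sees both regions), and an encoded gender covariate joins through
   learnable scalar weights `x~ = alpha_D x_D + alpha_G x_G` before the
   fully connected age head. Training minimizes MSE
   (`(1/n) sum |y_i - g_i|^2`); the reported metric is MAE in months.

Everything — attention, saliency with exact gradients, the cascade, the
fusion model, training — is implemented in R (+ a small C++ convolution
kernel), and a synthetic radiograph generator with planted, ground-truthed
discriminative regions makes the whole pipeline testable on one CPU in
minutes, with no downloads. Real data in the RSNA bone-age CSV dialect
(`id, boneage, male` + PNGs) drops in unchanged.

## Worked example

```r
library(osteoage)

# synthetic cohort: 500 hand-like images, age 12-216 months, +6 months
# for males, ground-truth region boxes known to the generator
p  <- synth_params(n_samples = 500, seed = 1)
ds <- generate_dataset(p)

# stage 1: cascaded region discovery with the analytic saliency fixture
toy <- toy_saliency_model(p)
res <- extract_cascade(toy, ds[[1]]$image)
res
#> <cascade_result> 2 region(s)
#> <region_box carpal rank=1 rows [32,61) cols [7,39)>
#> <region_box metacarpus_phalanx rank=2 rows [4,31) cols [25,58)>

# fixed-scale crops for every image
samples <- lapply(ds, function(s) {
  r <- extract_cascade(toy, s$image)
  list(id = s$id,
       crop_a = crop_fixed(s$image, r$boxes[[1]], c(32, 32)),
       crop_b = crop_fixed(s$image, r$boxes[[2]], c(32, 32)),
       male = s$male, age_months = s$age_months)
})

# stage 2: two-branch fusion regressor with gender pathway
cfg <- train_config(learning_rate = 2e-3, epochs = 40, batch_size = 16,
                    input_size = c(32, 32), seed = 1)
fit <- fit_bone_age(samples, use_gender = TRUE, use_cbam = TRUE, cfg = cfg)
fit
#> Two-branch bone age model
#>   gender pathway: TRUE  cbam: TRUE
#>   samples: train 400 / val 50 / test 50
#>   test MAE: 6.28 months
```

A held-out MAE of 6.28 months against a constant-predictor baseline of
47.7 months (13% of baseline) means the model explains almost all of the
planted age signal. Refitting with `use_gender = FALSE` and scoring both
models on a freshly simulated 300-sample cohort gives 6.51 months with
the gender pathway versus 6.81 without — the direction expected when a
genuine gender effect is dropped from the model. `predict(fit,
samples[1:3])` returns months; `plot(fit)` draws the training curves;
`coef(fit)` reports the learned fusion weights.

The same flow is scriptable from a shell via the bundled CLI
(`inst/cli/cascade-roi`): `synth`, `train-stage1`, `extract`,
`train-stage2`, `predict`, `evaluate`, and `ablate`, which writes the
four-arm (gender x CBAM) ablation table.

## Scope

The bundled backbones are small CNNs sized for CPU-scale experiments;
`xception`/`resnet50` are registered backbone names for users who wire in
external implementations. Training at full radiograph resolution on the
public RSNA cohort is out of scope here. DICOM ingestion is a documented
extension point only (PNG in, PNG/CSV/JSON out).
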