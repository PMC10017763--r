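# Synthetic hand-radiograph generator. Each image is a smooth hand
# silhouette plus two textured discs (a carpal-like and a
# metacarpus/phalanx-like region). The age signal is carried by texture
# grain size and edge sharpness inside the discs -- not by mean intensity,
# so localization cannot shortcut via global brightness -- mimicking how
# ossification detail, not exposure, encodes skeletal maturity. Pixels
# outside the discs carry no age information, and the observed label adds
# a gender offset plus Gaussian noise.

#' Synthetic dataset parameters
#'
#' Defaults define the package's desk-scale study conditions: 64 x 64
#' images, ages uniform over 12-216 months (the pediatric range of the
#' public RSNA cohort), a +6 month male offset, and mild pixel/label
#' noise.
#'
#' @param image_size `(h, w)` in pixels.
#' @param n_samples number of samples.
#' @param region_a,region_b lists with `center` (row, col; fractions of the
#'   image) and `radius` (pixels) for the carpal-like and
#'   metacarpus/phalanx-like discs.
#' @param jitter_px uniform positional jitter applied to each center.
#' @param age_range latent bone age range in months.
#' @param gender_effect months added to the label for male subjects.
#' @param noise_sd pixel noise standard deviation (intensity units).
#' @param label_noise_sd label noise standard deviation (months).
#' @param seed RNG seed for [generate_dataset()].
#' @return a `synth_params` list.
#' @export
synth_params <- function(image_size = c(64L, 64L), n_samples = 500L,
                         region_a = list(center = c(0.74, 0.34), radius = 13),
                         region_b = list(center = c(0.27, 0.62), radius = 12),
                         jitter_px = 2, age_range = c(12, 216),
                         gender_effect = 6, noise_sd = 0.01,
                         label_noise_sd = 2, seed = 1L) {
  p <- list(image_size = as.integer(image_size), n_samples = as.integer(n_samples),
            region_a = region_a, region_b = region_b, jitter_px = jitter_px,
            age_range = age_range, gender_effect = gender_effect,
            noise_sd = noise_sd, label_noise_sd = label_noise_sd,
            seed = as.integer(seed))
  ca <- region_a$center * image_size; cb <- region_b$center * image_size
  gap <- sqrt(sum((ca - cb)^2))
  if (gap < region_a$radius + region_b$radius + 2 * jitter_px)
    stop("infeasible geometry: regions can overlap after jitter")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(p, class = "synth_params")
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  g <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  ker <- outer(g, g); ker <- ker / sum(ker)
  cols <- cpp_im2col(array(x, c(dim(x), 1L)), k, (k - 1L) %/% 2L)
  matrix(as.vector(ker) %*% cols, nrow(x), ncol(x))
}

# compact-support disc: cosine ramp from 1 (inside) to exactly 0 beyond
# radius + edge_width, so no age-dependent tail leaks outside the region
soft_disc <- function(h, w, center, radius, edge_width) {
  d <- sqrt(outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, "+"))
  t <- (d - (radius - edge_width)) / (2 * edge_width)
  s <- 0.5 * (1 + cos(pi * pmin(pmax(t, 0), 1)))
  s
}

# smooth hand-like silhouette: palm ellipse + four finger lobes
hand_silhouette <- function(h, w) {
  sil <- matrix(0, h, w)
  ell <- function(c1, c2, r1, r2) {
    d <- sqrt(outer(((seq_len(h) - c1) / r1)^2, ((seq_len(w) - c2) / r2)^2, "+"))
    sigmoid((1 - d) * 3)   # soft outline: silhouette edges carry little texture energy
  }
  sil <- pmax(sil, ell(0.62 * h, 0.48 * w, 0.30 * h, 0.28 * w))
  for (f in 1:4)
    sil <- pmax(sil, ell(0.22 * h, (0.28 + 0.14 * (f - 1)) * w, 0.20 * h, 0.045 * w))
  sil
}

synth_image <- function(p, latent_age, centers) {
  h <- p$image_size[1]; w <- p$image_size[2]
  a_norm <- (latent_age - p$age_range[1]) / diff(p$age_range)
  # texture grain sigma (px): coarse young -> fine old, exponential so the
  # relative grain change per month is constant across the age range
  grain <- 2.0 * exp(-1.6 * a_norm)
  edge <- 2.5 * exp(-1.6 * a_norm)  # disc edge transition width (px)
  img <- 0.35 * hand_silhouette(h, w)
  img <- img + 0.05 * resize_bilinear(matrix(rnorm(64), 8, 8), h, w)
  regions <- list(list(c = centers$a, r = p$region_a$radius, amp = 0.30),
                  list(c = centers$b, r = p$region_b$radius, amp = 0.20))
  for (rg in regions) {
    s <- soft_disc(h, w, rg$c, rg$r, edge)
    tex <- gaussian_smooth(matrix(rnorm(h * w), h, w), grain)
    # unit spread, clipped at 2 sd so intensity clamping cannot eat the
    # planted variance contrast between the two discs
    tex <- pmin(pmax(tex / max(stats::sd(tex), 1e-8), -2), 2)
    img <- img * (1 - s) + s * (0.50 + rg$amp * tex)
  }
  if (p$noise_sd > 0) img <- img + rnorm(h * w, sd = p$noise_sd)
  # intensity floor just above 0: radiographs have nonzero background, and
  # exact 0 stays reserved as the black-mask sentinel
  pmin(pmax(img, 0.02), 1)
}

truth_box_for <- function(center, radius, h, w, role, rank, margin = 3) {
  region_box(max(0, floor(center[1] - 1 - radius - margin)),
             min(h, ceiling(center[1] - 1 + radius + margin) + 1),
             max(0, floor(center[2] - 1 - radius - margin)),
             min(w, ceiling(center[2] - 1 + radius + margin) + 1),
             role = role, rank = rank)
}

#' Generate a synthetic bone-age dataset
#'
#' Draws `p$n_samples` samples: latent age uniform over `p$age_range`,
#' disc centers jittered; the observed label is
#' `latent + gender_effect * male + N(0, label_noise_sd)`, clamped to the
#' age range. Gender is assigned age-matched: consecutive samples form
#' male/female pairs sharing one latent age (random order within the
#' pair), the matched-cohort design that identifies the gender effect
#' instead of confounding it with finite-sample age imbalance. Optionally
#' writes PNGs, an RSNA-dialect `labels.csv` (columns id, boneage, male)
#' and a `truth.json` with ground-truth boxes.
#'
#' @param p a [synth_params()] object.
#' @param dir optional output directory.
#' @return list of samples (class `synth_dataset`), each with `id`,
#'   `image`, `age_months` (observed label), `latent_age`, `male`, and
#'   `truth_boxes` (list of two [region_box()], carpal first).
#' @export
generate_dataset <- function(p, dir = NULL) {
  stopifnot(inherits(p, "synth_params"))
  h <- p$image_size[1]; w <- p$image_size[2]
  samples <- with_local_seed(p$seed, {
  n <- p$n_samples
  pair_age <- runif(ceiling(n / 2), p$age_range[1], p$age_range[2])
  ages <- rep(pair_age, each = 2)[seq_len(n)]
  first_male <- runif(ceiling(n / 2)) < 0.5
  males <- as.vector(rbind(first_male, !first_male))[seq_len(n)]
  lapply(seq_len(n), function(i) {
    a <- ages[i]
    male <- males[i]
    jit <- function(ctr) ctr * p$image_size +
      runif(2, -p$jitter_px, p$jitter_px)
    centers <- list(a = jit(p$region_a$center), b = jit(p$region_b$center))
    img <- synth_image(p, a, centers)
    label <- a + p$gender_effect * male + rnorm(1, sd = p$label_noise_sd)
    label <- min(max(label, p$age_range[1]), p$age_range[2])
    list(id = sprintf("synth%04d", i), image = img, age_months = label,
         latent_age = a, male = male,
         truth_boxes = list(
           truth_box_for(centers$a, p$region_a$radius, h, w, "carpal", 1L),
           truth_box_for(centers$b, p$region_b$radius, h, w,
                         "metacarpus_phalanx", 2L)))
  })
  })
  ds <- structure(samples, class = "synth_dataset", params = p)
  if (!is.null(dir)) write_synth_dataset(ds, dir)
  ds
}

#' @export
print.synth_dataset <- function(x, ...) {
  p <- attr(x, "params")
  cat("<synth_dataset>", length(x), "samples,",
      paste(p$image_size, collapse = "x"), "px, ages",
      paste(p$age_range, collapse = "-"), "months\n")
  invisible(x)
}

#' Toy saliency model
#'
#' A fixed analytic network whose Grad-CAM provably peaks on the most
#' textured planted disc: a local-variance map (gated to ignore windows
#' touching exactly-zero, i.e. black-masked, pixels), spatially averaged
#' by a fixed box kernel — emulating the low spatial resolution of CNN
#' saliency maps, so the peak attention area is a blob over the whole
#' textured region rather than a single speckle — then globally averaged
#' to a scalar texture-energy score. Used to exercise the cascade without
#' any training; the Grad-CAM source layer is the smoothed map (layer 2).
#'
#' @param p a [synth_params()] (supplies the input size).
#' @param win variance window (odd; default 5).
#' @param smooth box-smoothing kernel width (odd; default 15, about one
#'   planted-disc diameter at the default 64-pixel scale).
#' @return a scalar-output `osteo_net`.
#' @export
toy_saliency_model <- function(p, win = 5L, smooth = 15L) {
  stopifnot(smooth %% 2 == 1)
  sm <- layer_conv(1, 1, as.integer(smooth))
  sm$params$W <- array(1 / smooth^2, dim(sm$params$W))
  sm$params$b <- 0
  nn_sequential(layer_local_variance(win = win, zero_gate = TRUE),
                sm, layer_gap(),
                input_size = c(p$image_size, 1L))
}

write_synth_dataset <- function(ds, dir) {
  p <- attr(ds, "params")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in ds) png::writePNG(s$image, file.path(dir, paste0(s$id, ".png")))
  labels <- data.frame(id = vapply(ds, `[[`, "", "id"),
                       boneage = vapply(ds, `[[`, 0, "age_months"),
                       male = vapply(ds, `[[`, TRUE, "male"))
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  truth <- list(coordinates = coord_convention(),
                package_version = as.character(packageVersion("osteoage")),
                seed = p$seed,
                params = p[c("image_size", "n_samples", "age_range",
                             "gender_effect", "noise_sd", "label_noise_sd")],
                samples = lapply(ds, function(s)
                  list(id = s$id, latent_age = s$latent_age, male = s$male,
                       boxes = lapply(s$truth_boxes, unclass))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
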