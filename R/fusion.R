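# Stage-2 bone age regressor: branch A sees the carpal crop, branch B the
# metacarpus/phalanx crop. The two branch feature vectors are exchanged as
# a whole and concatenated (so each downstream path sees both regions),
# projected, concatenated into the region representation x_D, and fused
# with an encoded gender covariate x_G through learnable scalar weights:
# x~ = alpha_D * x_D + alpha_G * x_G, which feeds the fully connected age
# head. Removing the gender pathway or the CBAM blocks reproduces the four
# ablation arms (with/without gender x with/without CBAM) structurally.

backbone_registry <- function() c("small_cnn", "small_cnn_wide", "xception", "resnet50")

#' Branch configuration
#'
#' @param backbone_name one of `"small_cnn"`, `"small_cnn_wide"` (bundled
#'   trainable CNNs), or `"xception"` / `"resnet50"` (registered names for
#'   third-party backbones; constructing them errors unless such an
#'   implementation is available, which this installation does not
#'   bundle).
#' @param input_size `(h, w)` crop size the branch expects.
#' @param feature_dim branch output feature dimension.
#' @return a `branch_config`.
#' @export
branch_config <- function(backbone_name = "small_cnn", input_size = c(32L, 32L),
                          feature_dim = 16L) {
  if (!backbone_name %in% backbone_registry())
    stop("unknown backbone '", backbone_name, "'; registered backbones: ",
         paste(backbone_registry(), collapse = ", "))
  stopifnot(feature_dim > 0)
  structure(list(backbone_name = backbone_name,
                 input_size = as.integer(input_size),
                 feature_dim = as.integer(feature_dim)),
            class = "branch_config")
}

build_branch <- function(cfg, use_cbam) {
  ch <- switch(cfg$backbone_name,
               small_cnn = c(8L, 16L),
               small_cnn_wide = c(16L, 32L),
               stop("backbone '", cfg$backbone_name, "' is registered but not ",
                    "bundled with this package; use small_cnn or ",
                    "small_cnn_wide, or supply an external implementation"))
  layers <- list(layer_conv(1, ch[1], 3), layer_relu(), layer_maxpool2())
  if (use_cbam) layers <- c(layers, list(layer_cbam(ch[1], r = 4L)))
  # log-energy readout: texture grain is carried by energy ratios across
  # scales/filters, which become linear combinations after the log
  layers <- c(layers, list(layer_conv(ch[1], ch[2], 3), layer_relu(),
                           layer_maxpool2(),
                           layer_conv(ch[2], cfg$feature_dim, 3), layer_relu(),
                           layer_gap(), layer_log()))
  do.call(nn_sequential, c(layers, list(input_size = c(cfg$input_size, 1L))))
}

#' Gender encoder configuration
#'
#' A linear transformation of the binary male flag into a `d_g`-dimensional
#' embedding, later projected to the fused feature dimension.
#'
#' @param d_g embedding dimension (default 32).
#' @return a `gender_encoder` config.
#' @export
gender_encoder <- function(d_g = 32L) {
  stopifnot(d_g >= 1)
  structure(list(d_g = as.integer(d_g)), class = "gender_encoder")
}

#' Mid-fusion feature exchange
#'
#' Swaps the two branch feature vectors as a whole, then concatenates:
#' branch A's downstream path receives `c(feat_B, feat_A)` and branch B's
#' receives `c(feat_A, feat_B)`. Applying the swap twice restores the
#' original routing.
#'
#' @param feat_a,feat_b numeric feature vectors.
#' @return list with `path_a` and `path_b`, each of length
#'   `length(feat_a) + length(feat_b)`.
#' @export
exchange_and_concat <- function(feat_a, feat_b) {
  list(path_a = c(feat_b, feat_a), path_b = c(feat_a, feat_b))
}

#' Fuse region features with the gender embedding
#'
#' Computes `alpha_d * x_d + alpha_g * x_g`, the learnable-weighted sum of
#' the region representation and the projected gender embedding.
#'
#' @param x_d,x_g numeric vectors of equal length.
#' @param alpha_d,alpha_g scalar fusion weights.
#' @return fused numeric vector.
#' @export
fuse_gender <- function(x_d, x_g, alpha_d, alpha_g) {
  if (length(x_d) != length(x_g))
    stop("dimension mismatch: x_d has length ", length(x_d),
         " but x_g has length ", length(x_g),
         "; project both to a common dimension first")
  alpha_d * x_d + alpha_g * x_g
}

#' Build the two-branch fusion age model
#'
#' @param cfg_a,cfg_b [branch_config()] for the carpal and
#'   metacarpus/phalanx branches.
#' @param gender a [gender_encoder()].
#' @param use_cbam insert CBAM blocks into both branches.
#' @param use_gender keep the gender pathway (embedding, projection and
#'   the `alpha_G` fusion weight); `FALSE` removes it entirely.
#' @param p_dim per-path projection width (default 32).
#' @param head_hidden hidden width of the fully connected age head.
#' @return an untrained `fusion_model`.
#' @export
build_model <- function(cfg_a = branch_config(), cfg_b = branch_config(),
                        gender = gender_encoder(), use_cbam = TRUE,
                        use_gender = TRUE, p_dim = 32L, head_hidden = 32L) {
  stopifnot(inherits(cfg_a, "branch_config"), inherits(cfg_b, "branch_config"))
  dA <- cfg_a$feature_dim; dB <- cfg_b$feature_dim
  m <- list(
    branch_a = build_branch(cfg_a, use_cbam),
    branch_b = build_branch(cfg_b, use_cbam),
    proj_a = layer_dense(dA + dB, p_dim),
    proj_b = layer_dense(dA + dB, p_dim),
    head1 = layer_dense(2L * p_dim, head_hidden),
    head2 = layer_dense(head_hidden, 1L),
    cfg = list(cfg_a = cfg_a, cfg_b = cfg_b, use_cbam = use_cbam,
               use_gender = use_gender, d_g = gender$d_g,
               p_dim = as.integer(p_dim), head_hidden = as.integer(head_hidden)),
    target_center = 0, target_scale = 1)
  if (use_gender) {
    m$gender <- list(We = matrix(rnorm(gender$d_g, sd = 0.5), gender$d_g, 1),
                     be = numeric(gender$d_g),
                     Wg = matrix(he_init(gender$d_g, gender$d_g * 2 * p_dim),
                                 2 * p_dim, gender$d_g),
                     bg = numeric(2 * p_dim))
    m$alpha <- list(alpha_d = 1, alpha_g = 0.1)
  }
  structure(m, class = "fusion_model")
}

fusion_params <- function(m) {
  p <- list(branch_a = net_params(m$branch_a), branch_b = net_params(m$branch_b),
            proj_a = m$proj_a$params, proj_b = m$proj_b$params,
            head1 = m$head1$params, head2 = m$head2$params)
  if (m$cfg$use_gender) { p$gender <- m$gender; p$alpha <- m$alpha }
  p
}

fusion_set_params <- function(m, p) {
  m$branch_a <- net_set_params(m$branch_a, p$branch_a)
  m$branch_b <- net_set_params(m$branch_b, p$branch_b)
  m$proj_a$params <- p$proj_a; m$proj_b$params <- p$proj_b
  m$head1$params <- p$head1; m$head2$params <- p$head2
  if (m$cfg$use_gender) { m$gender <- p$gender; m$alpha <- p$alpha }
  m
}

check_crop <- function(crop, size, what) {
  if (!is.matrix(crop) || !all(dim(crop) == size))
    stop(what, " crop has size ", paste(dim(crop), collapse = "x"),
         " but the model expects ", paste(size, collapse = "x"))
}

fusion_forward <- function(m, crop_a, crop_b, male, keep = FALSE) {
  check_crop(crop_a, m$cfg$cfg_a$input_size, "carpal")
  check_crop(crop_b, m$cfg$cfg_b$input_size, "metacarpus_phalanx")
  fa <- nn_forward(m$branch_a, array(crop_a, c(dim(crop_a), 1L)), keep = keep)
  fb <- nn_forward(m$branch_b, array(crop_b, c(dim(crop_b), 1L)), keep = keep)
  ex <- exchange_and_concat(fa$out, fb$out)
  ua <- drop(m$proj_a$params$W %*% ex$path_a) + m$proj_a$params$b
  ub <- drop(m$proj_b$params$W %*% ex$path_b) + m$proj_b$params$b
  ha <- pmax(ua, 0); hb <- pmax(ub, 0)
  xd <- c(ha, hb)
  if (m$cfg$use_gender) {
    e <- drop(m$gender$We * male) + m$gender$be
    xg <- drop(m$gender$Wg %*% e) + m$gender$bg
    x <- fuse_gender(xd, xg, m$alpha$alpha_d, m$alpha$alpha_g)
  } else {
    e <- xg <- NULL
    x <- xd
  }
  u1 <- drop(m$head1$params$W %*% x) + m$head1$params$b
  h1 <- pmax(u1, 0)
  out <- drop(m$head2$params$W %*% h1) + m$head2$params$b
  res <- list(out = out)
  if (keep)
    res$cache <- list(fa = fa, fb = fb, ex = ex, ua = ua, ub = ub, ha = ha,
                      hb = hb, xd = xd, e = e, xg = xg, x = x, u1 = u1,
                      h1 = h1, male = male)
  res
}

fusion_backward <- function(m, cache, g) {
  cg <- cache
  dW2 <- matrix(g * cg$h1, 1); db2 <- g
  dh1 <- drop(crossprod(m$head2$params$W, g))
  du1 <- dh1 * (cg$u1 > 0)
  dW1 <- du1 %o% cg$x; db1 <- du1
  dx <- drop(crossprod(m$head1$params$W, du1))
  grads <- list(head1 = list(W = dW1, b = db1), head2 = list(W = dW2, b = db2))
  if (m$cfg$use_gender) {
    grads$alpha <- list(alpha_d = sum(dx * cg$xd), alpha_g = sum(dx * cg$xg))
    dxd <- m$alpha$alpha_d * dx
    dxg <- m$alpha$alpha_g * dx
    de <- drop(crossprod(m$gender$Wg, dxg))
    grads$gender <- list(We = matrix(de * cg$male, ncol = 1), be = de,
                         Wg = dxg %o% cg$e, bg = dxg)
  } else dxd <- dx
  p <- m$cfg$p_dim
  dha <- dxd[1:p]; dhb <- dxd[(p + 1):(2 * p)]
  dua <- dha * (cg$ua > 0); dub <- dhb * (cg$ub > 0)
  grads$proj_a <- list(W = dua %o% cg$ex$path_a, b = dua)
  grads$proj_b <- list(W = dub %o% cg$ex$path_b, b = dub)
  dina <- drop(crossprod(m$proj_a$params$W, dua))
  dinb <- drop(crossprod(m$proj_b$params$W, dub))
  dA <- m$cfg$cfg_a$feature_dim; dB <- m$cfg$cfg_b$feature_dim
  dfa <- dina[(dB + 1):(dB + dA)] + dinb[1:dA]
  dfb <- dina[1:dB] + dinb[(dA + 1):(dA + dB)]
  grads$branch_a <- nn_backward(m$branch_a, cg$fa$caches, dfa)$grads
  grads$branch_b <- nn_backward(m$branch_b, cg$fb$caches, dfb)$grads
  grads
}

#' Predict bone age for one pair of crops
#'
#' Deterministic forward pass of a [build_model()] network.
#'
#' @param model a `fusion_model` (trained or not).
#' @param crop_carpal,crop_metaphal grayscale matrices sized per the
#'   model's branch configurations.
#' @param male logical gender flag.
#' @return predicted age in months (scalar).
#' @export
predict_age <- function(model, crop_carpal, crop_metaphal, male) {
  stopifnot(inherits(model, "fusion_model"))
  out <- fusion_forward(model, crop_carpal, crop_metaphal, as.numeric(male))$out
  out * model$target_scale + model$target_center
}

#' Number of trainable parameters of a model
#'
#' @param model a `fusion_model` or `osteo_net`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  p <- if (inherits(model, "fusion_model")) fusion_params(model)
       else net_params(model)
  sum(unlist(rapply(p, length, how = "unlist")))
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model>", x$cfg$cfg_a$backbone_name, "+",
      x$cfg$cfg_b$backbone_name,
      "| cbam:", x$cfg$use_cbam, "| gender:", x$cfg$use_gender,
      "|", n_params(x), "parameters\n")
  invisible(x)
}
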