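# Convolutional block attention (CBAM): channel attention from globally
# pooled descriptors through a shared MLP, then spatial attention from
# channel-pooled maps through a 7x7 convolution. These are the standalone,
# array-level operations; layer_cbam() embeds the same computation in a
# trainable network and is cross-checked against these in the tests.

#' Construct a feature volume
#'
#' A feature volume is a 3-D numeric array laid out `(height, width,
#' channel)` — the activation block of one convolutional layer. All
#' dimensions must be at least 1 and all values finite.
#'
#' @param values 3-D numeric array `(height, width, channel)`.
#' @return the validated array with class `feature_volume`.
#' @export
feature_volume <- function(values) {
  if (!(is.array(values) && length(dim(values)) == 3))
    stop("feature volume must be a 3-D (height, width, channel) array")
  if (any(dim(values) < 1)) stop("all feature volume dimensions must be >= 1")
  if (!all(is.finite(values))) stop("feature volume contains non-finite values")
  structure(values, class = c("feature_volume", class(values)))
}

#' Shared two-layer perceptron for channel attention
#'
#' The same pair of linear maps is applied to the average-pooled and the
#' max-pooled channel descriptor: `W0` reduces `n_channels` to
#' `n_channels / r`, `W1` maps back up. A hidden ReLU sits between them by
#' default (standard CBAM practice); set `relu = FALSE` for the plain
#' weight-only composition. Bias vectors are absent unless supplied.
#'
#' @param n_channels channel count of the feature volumes this MLP serves.
#' @param r reduction ratio; must divide `n_channels`. Default 16.
#' @param W0,W1 optional explicit weight matrices (`n_channels/r` x
#'   `n_channels` and `n_channels` x `n_channels/r`); random He init if
#'   omitted.
#' @param b0,b1 optional bias vectors.
#' @param relu apply ReLU between `W0` and `W1` (default `TRUE`).
#' @return an object of class `shared_mlp`.
#' @seealso [identity_mlp()] for the r = 1 identity fixture.
#' @export
shared_mlp <- function(n_channels, r = 16L, W0 = NULL, W1 = NULL,
                       b0 = NULL, b1 = NULL, relu = TRUE) {
  if (n_channels %% r != 0)
    stop("reduction ratio r = ", r, " must divide n_channels = ", n_channels)
  hid <- n_channels / r
  if (is.null(W0)) W0 <- matrix(he_init(n_channels, hid * n_channels), hid, n_channels)
  if (is.null(W1)) W1 <- matrix(he_init(hid, n_channels * hid), n_channels, hid)
  stopifnot(nrow(W0) == hid, ncol(W0) == n_channels,
            nrow(W1) == n_channels, ncol(W1) == hid)
  structure(list(n_channels = as.integer(n_channels), r = as.integer(r),
                 W0 = W0, W1 = W1, b0 = b0, b1 = b1, relu = relu),
            class = "shared_mlp")
}

#' @rdname shared_mlp
#' @export
identity_mlp <- function(n_channels) {
  shared_mlp(n_channels, r = 1L, W0 = diag(n_channels), W1 = diag(n_channels),
             relu = FALSE)
}

apply_shared_mlp <- function(mlp, s) {
  u <- drop(mlp$W0 %*% s)
  if (!is.null(mlp$b0)) u <- u + mlp$b0
  if (mlp$relu) u <- pmax(u, 0)
  o <- drop(mlp$W1 %*% u)
  if (!is.null(mlp$b1)) o <- o + mlp$b1
  o
}

#' Channel attention weights
#'
#' Computes one sigmoid weight per channel:
#' `sigma(MLP(AvgPool(F)) + MLP(MaxPool(F)))`, where the pools are global
#' spatial average and maximum per channel and the MLP is shared between
#' the two descriptors.
#'
#' @param f feature volume (3-D `(height, width, channel)` array).
#' @param mlp a [shared_mlp()] whose dimensions match `f`'s channel count.
#' @return numeric vector of length `n_channels`, each entry strictly in
#'   (0, 1).
#' @export
channel_attention <- function(f, mlp) {
  f <- feature_volume(unclass(f))
  C <- dim(f)[3]
  if (mlp$n_channels != C)
    stop("shared MLP expects ", mlp$n_channels, " channels but feature volume has ", C)
  m <- matrix(f, prod(dim(f)[1:2]), C)
  s_avg <- colMeans(m)
  s_max <- apply(m, 2, max)
  sigmoid(apply_shared_mlp(mlp, s_avg) + apply_shared_mlp(mlp, s_max))
}

#' Spatial attention weights
#'
#' Pools the feature volume across channels into a two-channel map
#' (per-pixel channel mean and channel max), convolves it with a single
#' 7x7 kernel (zero padding 3, so the spatial shape is preserved), and
#' applies a sigmoid.
#'
#' @param f feature volume.
#' @param kernel numeric array `7 x 7 x 2` (or `7 x 7 x 2 x 1`): the
#'   convolution weights over the stacked average and maximum maps.
#' @param bias scalar bias added before the sigmoid (default 0).
#' @return numeric matrix with `f`'s spatial shape, entries strictly in
#'   (0, 1).
#' @export
spatial_attention <- function(f, kernel, bias = 0) {
  f <- feature_volume(unclass(f))
  if (length(dim(kernel)) == 4) {
    if (!all(dim(kernel) == c(7, 7, 2, 1))) stop("kernel must be 7x7x2 (x1)")
    kernel <- array(kernel, c(7, 7, 2))
  }
  if (!all(dim(kernel) == c(7, 7, 2))) stop("kernel must be 7x7x2")
  d <- dim(f)
  m <- matrix(f, d[1] * d[2], d[3])
  p_avg <- rowMeans(m)
  p_max <- m[, 1]
  if (d[3] > 1) for (c in 2:d[3]) p_max <- pmax(p_max, m[, c])
  S <- array(c(p_avg, p_max), c(d[1], d[2], 2L))
  cols <- cpp_im2col(S, 7L, 3L)
  z <- drop(crossprod(matrix(kernel, 7 * 7 * 2), cols)) + bias
  matrix(sigmoid(z), d[1], d[2])
}

#' Apply a CBAM block to a feature volume
#'
#' Sequential channel-then-spatial refinement: the volume is first scaled
#' per channel by its channel-attention weights, then the refined volume is
#' scaled per pixel by its spatial-attention weights. The output has the
#' input's shape.
#'
#' @inheritParams spatial_attention
#' @param mlp a [shared_mlp()] for the channel stage.
#' @return feature volume with the same dimensions as `f`.
#' @export
apply_cbam <- function(f, mlp, kernel, bias = 0) {
  f <- feature_volume(unclass(f))
  d <- dim(f)
  mc <- channel_attention(f, mlp)
  refined <- unclass(f) * rep(mc, each = d[1] * d[2])
  ms <- spatial_attention(feature_volume(refined), kernel, bias)
  feature_volume(refined * as.vector(ms))
}
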