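# Minimal sequential CNN engine with exact manual backpropagation.
#
# All spatial tensors are (height, width, channel) arrays, column-major.
# Convolutions are cross-correlations (no kernel flip), stride 1, zero
# padding; downsampling is done by pooling layers. Every layer's backward
# pass is closed-form and is validated against central finite differences
# in the test suite.

new_layer <- function(type, params = list(), ...) {
  structure(c(list(type = type, params = params), list(...)),
            class = c(paste0("layer_", type), "nn_layer"))
}

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

#' Network layer constructors
#'
#' Building blocks for [nn_sequential()] networks: 2-D convolution
#' (`layer_conv`), rectified linear activation (`layer_relu`), 2x2 max
#' pooling (`layer_maxpool2`), global average pooling to a channel vector
#' (`layer_gap`), flattening (`layer_flatten`), a fully connected layer
#' (`layer_dense`), a convolutional block attention module
#' (`layer_cbam`), and an analytic local-variance map (`layer_local_variance`,
#' parameter free; used by the toy saliency model).
#'
#' Weights are He-initialized from the current RNG stream; seed before
#' construction for reproducibility.
#'
#' @param in_ch,out_ch,k convolution geometry; padding defaults to
#'   `floor(k / 2)` so odd kernels preserve shape.
#' @param pad zero padding width.
#' @param d_in,d_out dense layer dimensions.
#' @param channels,r CBAM channel count and reduction ratio (`r` must divide
#'   `channels`).
#' @param mlp_relu,mlp_bias CBAM shared-MLP options: hidden ReLU between the
#'   two linear maps (standard CBAM; settable off) and bias terms (off by
#'   default, matching the weight-only two-map form).
#' @param win local-variance window (odd).
#' @return a layer object for [nn_sequential()].
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv <- function(in_ch, out_ch, k, pad = floor(k / 2)) {
  new_layer("conv",
            params = list(W = array(he_init(in_ch * k * k, k * k * in_ch * out_ch),
                                    c(k, k, in_ch, out_ch)),
                          b = numeric(out_ch)),
            k = k, pad = pad, in_ch = in_ch, out_ch = out_ch)
}

#' @rdname layers
#' @export
layer_relu <- function() new_layer("relu")

#' @rdname layers
#' @export
layer_maxpool2 <- function() new_layer("maxpool2")

#' @rdname layers
#' @export
layer_gap <- function() new_layer("gap")

#' @rdname layers
#' @export
layer_flatten <- function() new_layer("flatten")

#' @rdname layers
#' @param eps stabilizer added inside the logarithm.
#' @export
layer_log <- function(eps = 1e-6) new_layer("log", eps = eps)

#' @rdname layers
#' @export
layer_dense <- function(d_in, d_out) {
  new_layer("dense",
            params = list(W = matrix(he_init(d_in, d_in * d_out), d_out, d_in),
                          b = numeric(d_out)),
            d_in = d_in, d_out = d_out)
}

#' @rdname layers
#' @export
layer_cbam <- function(channels, r = 16L, mlp_relu = TRUE, mlp_bias = FALSE) {
  if (channels %% r != 0)
    stop("reduction ratio r = ", r, " must divide channels = ", channels)
  hid <- channels / r
  params <- list(
    W0 = matrix(he_init(channels, hid * channels), hid, channels),
    W1 = matrix(he_init(hid, channels * hid), channels, hid),
    K7 = array(rnorm(7 * 7 * 2, sd = sqrt(2 / (7 * 7 * 2))), c(7, 7, 2, 1)),
    b7 = 0)
  if (mlp_bias) {
    params$b0 <- numeric(hid)
    params$b1 <- numeric(channels)
  }
  new_layer("cbam", params = params, channels = channels, r = r,
            mlp_relu = mlp_relu, mlp_bias = mlp_bias)
}

#' @rdname layers
#' @param zero_gate if `TRUE`, the variance map is zeroed wherever the
#'   window touches an exactly-zero pixel, so black-masked regions (and the
#'   rim around them) are treated as invalid rather than as high-contrast
#'   edges.
#' @export
layer_local_variance <- function(win = 5L, zero_gate = FALSE) {
  stopifnot(win %% 2 == 1)
  new_layer("local_variance", win = as.integer(win), zero_gate = zero_gate)
}

#' Assemble a sequential network
#'
#' @param ... layer objects, applied in order.
#' @param input_size `(h, w, channels)` the network expects.
#' @return an object of class `osteo_net`.
#' @export
nn_sequential <- function(..., input_size) {
  structure(list(layers = list(...), input_size = as.integer(input_size)),
            class = "osteo_net")
}

#' @export
print.osteo_net <- function(x, ...) {
  cat("<osteo_net> input", paste(x$input_size, collapse = "x"),
      "-", length(x$layers), "layers:",
      paste(vapply(x$layers, `[[`, "", "type"), collapse = " -> "), "\n")
  invisible(x)
}

# ---- per-layer forward ------------------------------------------------

conv_forward <- function(layer, x) {
  k <- layer$k
  cols <- cpp_im2col(x, as.integer(k), as.integer(layer$pad))
  Wmat <- matrix(layer$params$W, nrow = k * k * layer$in_ch)
  ho <- dim(x)[1] + 2 * layer$pad - k + 1
  wo <- dim(x)[2] + 2 * layer$pad - k + 1
  om <- crossprod(Wmat, cols) + layer$params$b   # out_ch x P, bias recycled
  out <- array(t(om), c(ho, wo, layer$out_ch))
  list(out = out, cache = list(cols = cols, dim_in = dim(x)))
}

conv_backward <- function(layer, cache, g) {
  k <- layer$k
  P <- prod(dim(g)[1:2])
  Gmat <- matrix(g, P, layer$out_ch)
  dW <- array(cache$cols %*% Gmat, dim(layer$params$W))
  db <- colSums(Gmat)
  Wmat <- matrix(layer$params$W, nrow = k * k * layer$in_ch)
  dcols <- Wmat %*% t(Gmat)
  dx <- cpp_col2im(dcols, cache$dim_in[1], cache$dim_in[2], cache$dim_in[3],
                   as.integer(k), as.integer(layer$pad))
  list(dx = dx, grads = list(W = dW, b = db))
}

cbam_mlp <- function(layer, s) {
  p <- layer$params
  u <- drop(p$W0 %*% s)
  if (!is.null(p$b0)) u <- u + p$b0
  h <- if (layer$mlp_relu) pmax(u, 0) else u
  o <- drop(p$W1 %*% h)
  if (!is.null(p$b1)) o <- o + p$b1
  list(u = u, h = h, o = o)
}

cbam_forward <- function(layer, x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  m <- matrix(x, HW, C)
  savg <- colMeans(m)
  imax <- max.col(t(m), ties.method = "first")
  smax <- m[cbind(imax, seq_len(C))]
  pa <- cbam_mlp(layer, savg)
  pm <- cbam_mlp(layer, smax)
  a <- pa$o + pm$o
  Mc <- sigmoid(a)
  mR1 <- m * rep(Mc, each = HW)
  pavg <- rowMeans(mR1)
  rmax_i <- max.col(mR1, ties.method = "first")
  rmax <- mR1[cbind(seq_len(HW), rmax_i)]
  S <- array(c(pavg, rmax), c(d[1], d[2], 2L))
  cols7 <- cpp_im2col(S, 7L, 3L)
  z <- drop(crossprod(matrix(layer$params$K7, nrow = 7 * 7 * 2), cols7)) +
    layer$params$b7
  Ms <- sigmoid(z)                      # length HW
  mOut <- mR1 * Ms
  list(out = array(mOut, d),
       cache = list(d = d, m = m, savg = savg, smax = smax, imax = imax,
                    pa = pa, pm = pm, Mc = Mc, mR1 = mR1, rmax_i = rmax_i,
                    cols7 = cols7, Ms = Ms))
}

cbam_backward <- function(layer, cache, g) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]
  p <- layer$params
  mg <- matrix(g, HW, C)
  dMs <- rowSums(mg * cache$mR1)
  dmR1 <- mg * cache$Ms
  dz <- dMs * cache$Ms * (1 - cache$Ms)
  # 7x7 conv backward (2 input channels, 1 output channel)
  K7mat <- matrix(p$K7, nrow = 7 * 7 * 2)
  dK7 <- array(cache$cols7 %*% dz, dim(p$K7))
  db7 <- sum(dz)
  dcols7 <- K7mat %*% t(matrix(dz, HW, 1))
  dS <- cpp_col2im(dcols7, d[1], d[2], 2L, 7L, 3L)
  dpavg <- as.vector(dS[, , 1]); drmax <- as.vector(dS[, , 2])
  dmR1 <- dmR1 + dpavg / C
  idx <- cbind(seq_len(HW), cache$rmax_i)
  dmR1[idx] <- dmR1[idx] + drmax
  dMc <- colSums(dmR1 * cache$m)
  dm <- dmR1 * rep(cache$Mc, each = HW)
  da <- dMc * cache$Mc * (1 - cache$Mc)
  mlp_back <- function(path, s, da) {
    dW1 <- da %o% path$h
    db1 <- da
    dh <- drop(crossprod(p$W1, da))
    du <- if (layer$mlp_relu) dh * (path$u > 0) else dh
    dW0 <- du %o% s
    db0 <- du
    ds <- drop(crossprod(p$W0, du))
    list(dW0 = dW0, db0 = db0, dW1 = dW1, db1 = db1, ds = ds)
  }
  ba <- mlp_back(cache$pa, cache$savg, da)
  bm <- mlp_back(cache$pm, cache$smax, da)
  dm <- dm + rep(ba$ds / HW, each = HW)
  midx <- cbind(cache$imax, seq_len(C))
  dm[midx] <- dm[midx] + bm$ds
  grads <- list(W0 = ba$dW0 + bm$dW0, W1 = ba$dW1 + bm$dW1,
                K7 = dK7, b7 = db7)
  if (!is.null(p$b0)) {
    grads$b0 <- ba$db0 + bm$db0
    grads$b1 <- ba$db1 + bm$db1
  }
  list(dx = array(dm, d), grads = grads)
}

lvar_forward <- function(layer, x) {
  d <- dim(x); C <- d[3]
  mns <- vector("list", C)
  v <- matrix(0, d[1], d[2])
  gate <- matrix(1, d[1], d[2])
  for (c in seq_len(C)) {
    mn <- box_mean(x[, , c], layer$win)
    v <- v + pmax(box_mean(x[, , c]^2, layer$win) - mn^2, 0)
    mns[[c]] <- mn
    if (isTRUE(layer$zero_gate))
      gate <- gate * (box_sum((x[, , c] == 0) * 1, layer$win) == 0)
  }
  v <- v / C * gate
  v[v <= 1e-14] <- 0      # squash fp residue so constants map to exact zero
  list(out = array(v, c(d[1], d[2], 1L)),
       cache = list(x = x, mns = mns, gate = gate))
}

lvar_backward <- function(layer, cache, g) {
  gm <- cache$x * 0
  d2 <- dim(cache$x)[1:2]
  cnt <- box_count(d2, layer$win)
  g2 <- matrix(g, d2[1], d2[2]) * cache$gate / cnt
  C <- dim(cache$x)[3]
  bg <- box_sum(g2, layer$win)
  for (c in seq_len(C)) {
    gm[, , c] <- (2 * cache$x[, , c] * bg -
                    2 * box_sum(g2 * cache$mns[[c]], layer$win)) / C
  }
  list(dx = gm, grads = list())
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = conv_forward(layer, x),
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    maxpool2 = {
      r <- cpp_maxpool2(x)
      list(out = r$out, cache = list(argmax = r$argmax, dim_in = dim(x)))
    },
    gap = list(out = as.vector(colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))),
               cache = list(dim_in = dim(x))),
    flatten = list(out = as.vector(x), cache = list(dim_in = dim(x))),
    dense = list(out = drop(layer$params$W %*% x) + layer$params$b,
                 cache = list(x = x)),
    log = list(out = log(x + layer$eps), cache = list(x = x)),
    cbam = cbam_forward(layer, x),
    local_variance = lvar_forward(layer, x),
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, g) {
  switch(layer$type,
    conv = conv_backward(layer, cache, g),
    relu = list(dx = g * cache$mask, grads = list()),
    maxpool2 = {
      dx <- array(0, cache$dim_in)
      dx[as.vector(cache$argmax)] <- dx[as.vector(cache$argmax)] + as.vector(g)
      list(dx = dx, grads = list())
    },
    gap = {
      HW <- prod(cache$dim_in[1:2])
      list(dx = array(rep(g / HW, each = HW), cache$dim_in), grads = list())
    },
    flatten = list(dx = array(g, cache$dim_in), grads = list()),
    dense = list(dx = drop(crossprod(layer$params$W, g)),
                 grads = list(W = g %o% cache$x, b = g)),
    log = list(dx = g / (cache$x + layer$eps), grads = list()),
    cbam = cbam_backward(layer, cache, g),
    local_variance = lvar_backward(layer, cache, g),
    stop("unknown layer type: ", layer$type))
}

# ---- whole-network passes ---------------------------------------------

# Forward pass; returns final output, per-layer caches, and per-layer
# outputs (acts[[l]] is the output of layer l).
nn_forward <- function(net, x, keep = TRUE) {
  caches <- acts <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[l]], x)
    x <- r$out
    if (keep) {
      caches[[l]] <- r$cache
      acts[[l]] <- x
    }
  }
  list(out = x, caches = caches, acts = acts)
}

# Resume a forward pass treating `act` as the output of layer `from`.
nn_forward_from <- function(net, from, act) {
  x <- act
  if (from < length(net$layers))
    for (l in (from + 1):length(net$layers)) x <- layer_forward(net$layers[[l]], x)$out
  x
}

# Backward pass from gradient `g` at the network output. Returns gradient
# lists per layer (named like each layer's params), the input gradient, and
# boundary gradients (bnd[[l]] = dL/d output of layer l).
nn_backward <- function(net, caches, g) {
  L <- length(net$layers)
  grads <- bnd <- vector("list", L)
  for (l in L:1) {
    bnd[[l]] <- g
    r <- layer_backward(net$layers[[l]], caches[[l]], g)
    grads[[l]] <- r$grads
    g <- r$dx
  }
  list(grads = grads, dx = g, bnd = bnd)
}

# ---- parameter plumbing ------------------------------------------------

net_params <- function(net) lapply(net$layers, function(l) l$params)

net_set_params <- function(net, params) {
  for (l in seq_along(net$layers)) net$layers[[l]]$params <- params[[l]]
  net
}

# Adam over a nested list of parameter arrays mirrored by gradient arrays.
adam_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      # unnamed list levels (layer index)
      if (is.null(names(p))) {
        for (i in seq_along(p)) {
          if (is.null(g[[i]]) || length(g[[i]]) == 0) next
          r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
          out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
        }
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    mh <- m2 / (1 - beta1^t)
    vh <- v2 / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise accumulate two nested grad lists (a may be NULL)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.list(b[[i]])) a[[i]] <- grads_add(a[[i]], b[[i]])
    else a[[i]] <- a[[i]] + b[[i]]
  }
  a
}

grads_scale <- function(g, s) rapply(g, function(x) x * s, how = "replace")
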