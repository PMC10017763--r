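# Loop-based reference implementations, deliberately independent of the
# package's vectorized code paths.

oracle_channel_attention <- function(f, mlp) {
  C <- dim(f)[3]
  out <- numeric(C)
  s_avg <- s_max <- numeric(C)
  for (c in seq_len(C)) {
    vals <- c()
    for (i in seq_len(dim(f)[1]))
      for (j in seq_len(dim(f)[2])) vals <- c(vals, f[i, j, c])
    s_avg[c] <- mean(vals)
    s_max[c] <- max(vals)
  }
  mlp_one <- function(s) {
    u <- as.vector(mlp$W0 %*% s)
    if (!is.null(mlp$b0)) u <- u + mlp$b0
    if (mlp$relu) u <- ifelse(u > 0, u, 0)
    o <- as.vector(mlp$W1 %*% u)
    if (!is.null(mlp$b1)) o <- o + mlp$b1
    o
  }
  a <- mlp_one(s_avg) + mlp_one(s_max)
  1 / (1 + exp(-a))
}

# direct 2-D cross-correlation of the stacked channel-avg/channel-max maps
oracle_spatial_attention <- function(f, kernel, bias = 0) {
  H <- dim(f)[1]; W <- dim(f)[2]; C <- dim(f)[3]
  p_avg <- p_max <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- f[i, j, ]
    p_avg[i, j] <- mean(v)
    p_max[i, j] <- max(v)
  }
  S <- list(p_avg, p_max)
  z <- matrix(bias, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    for (di in 1:7) for (dj in 1:7) for (ch in 1:2) {
      ri <- i + di - 4; cj <- j + dj - 4
      if (ri >= 1 && ri <= H && cj >= 1 && cj <= W)
        z[i, j] <- z[i, j] + kernel[di, dj, ch] * S[[ch]][ri, cj]
    }
  1 / (1 + exp(-z))
}

oracle_conv2d <- function(x, W, b, pad) {
  # x: (H, W, Cin); W: (k, k, Cin, Cout); stride 1
  H <- dim(x)[1]; Wd <- dim(x)[2]; k <- dim(W)[1]
  Ho <- H + 2 * pad - k + 1; Wo <- Wd + 2 * pad - k + 1
  out <- array(0, c(Ho, Wo, dim(W)[4]))
  for (o in seq_len(dim(W)[4])) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- b[o]
    for (di in seq_len(k)) for (dj in seq_len(k)) for (ci in seq_len(dim(x)[3])) {
      ri <- i + di - 1 - pad; cj <- j + dj - 1 - pad
      if (ri >= 1 && ri <= H && cj >= 1 && cj <= Wd)
        acc <- acc + W[di, dj, ci, o] * x[ri, cj, ci]
    }
    out[i, j, o] <- acc
  }
  out
}

# exhaustive flood fill from the global max (row-major tie-break),
# 8-connectivity, used to cross-check locate_peak_region
oracle_peak_component <- function(v, frac) {
  H <- nrow(v); W <- ncol(v)
  best <- -Inf; seed <- c(1, 1)
  for (i in seq_len(H)) for (j in seq_len(W))
    if (v[i, j] > best) { best <- v[i, j]; seed <- c(i, j) }
  mask <- v >= frac * best
  comp <- matrix(FALSE, H, W)
  queue <- list(seed)
  comp[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (di in -1:1) for (dj in -1:1) {
      ri <- cur[1] + di; cj <- cur[2] + dj
      if (ri >= 1 && ri <= H && cj >= 1 && cj <= W &&
          mask[ri, cj] && !comp[ri, cj]) {
        comp[ri, cj] <- TRUE
        queue <- c(queue, list(c(ri, cj)))
      }
    }
  }
  comp
}

random_volume <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(rnorm(h * w * c), c(h, w, c))
}

box_contains_point <- function(b, r, c) {
  r >= b$row_start && r <= b$row_end && c >= b$col_start && c <= b$col_end
}
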