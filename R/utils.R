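sigmoid <- function(x) 1 / (1 + exp(-x))

#' Bilinear resize of a 2-D image
#'
#' Resamples a numeric matrix to a target size with bilinear interpolation
#' using half-pixel-center alignment (destination pixel `d` samples source
#' coordinate `(d + 0.5) * scale - 0.5`, clamped to the image).
#'
#' @param x numeric matrix.
#' @param out_h,out_w positive integer output dimensions.
#' @return numeric matrix of dimension `out_h` by `out_w`.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  stopifnot(is.matrix(x), out_h >= 1, out_w >= 1)
  cpp_bilinear_resize(x, as.integer(out_h), as.integer(out_w))
}

# Rotate a [0,1] image about its center by `angle` degrees
# (counter-clockwise), bilinear sampling, zero fill outside.
rotate_image <- function(x, angle) {
  if (angle == 0) return(x)
  h <- nrow(x); w <- ncol(x)
  th <- angle * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  # inverse map: destination (r, c) pulls from source rotated by -angle
  dst <- expand.grid(r = seq_len(h) - 1, c = seq_len(w) - 1)
  dr <- dst$r - cy; dc <- dst$c - cx
  sr <- cos(th) * dr - sin(th) * dc + cy
  sc <- sin(th) * dr + cos(th) * dc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- numeric(h * w)
  at <- function(ri, ci) {
    ok <- ri >= 0 & ri <= h - 1 & ci >= 0 & ci <= w - 1
    v <- numeric(length(ri))
    v[ok] <- x[cbind(ri[ok] + 1, ci[ok] + 1)]
    v
  }
  val <- (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) +
    fr * fc * at(r0 + 1, c0 + 1)
  matrix(val, h, w)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

coord_convention <- function() "0-based, half-open, row-major"

box_sum <- function(x, win) {
  stopifnot(is.matrix(x), win >= 1, win %% 2 == 1)
  cols <- cpp_im2col(array(x, c(dim(x), 1L)), as.integer(win),
                     as.integer((win - 1) / 2))
  matrix(colSums(cols), nrow(x), ncol(x))
}

# local mean over a win x win window, normalized by the number of
# in-bounds pixels so border windows are true means (a constant image has
# exactly constant local mean everywhere)
box_mean <- function(x, win) {
  box_sum(x, win) / box_count(dim(x), win)
}

box_count <- local({
  cache <- new.env(parent = emptyenv())
  function(d, win) {
    key <- paste(d[1], d[2], win)
    if (is.null(cache[[key]]))
      cache[[key]] <- box_sum(matrix(1, d[1], d[2]), win)
    cache[[key]]
  }
})
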