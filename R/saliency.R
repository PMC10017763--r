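# Grad-CAM saliency for the region-extraction stage. The "score" that is
# differentiated is the network's scalar output (here: predicted age, or
# the toy model's texture-energy score); channel weights are the global
# average of that score's gradient on the chosen layer's activations.

#' Grad-CAM heat map
#'
#' Computes a gradient-weighted class-activation heat map for a scalar
#' output network: per-channel weights are the spatial average of
#' d(output)/d(activation) at the chosen layer, the weighted channel sum is
#' rectified, bilinearly upsampled to the input image size and normalized
#' so its maximum is exactly 1 (an identically zero raw map stays all
#' zero).
#'
#' @param model an `osteo_net` (see [nn_sequential()]).
#' @param image numeric matrix (grayscale, `[0,1]`) or `(h, w, c)` array
#'   matching the model input.
#' @param layer index of the source layer; defaults to the last layer that
#'   produces a spatial (3-D) activation volume.
#' @return an object of class `heat_map`: list with `values` (matrix the
#'   size of `image`, in `[0,1]`) and `source_layer`.
#' @export
grad_cam <- function(model, image, layer = NULL) {
  stopifnot(inherits(model, "osteo_net"))
  x <- if (is.matrix(image)) array(image, c(dim(image), 1L)) else image
  fw <- nn_forward(model, x)
  if (length(fw$out) != 1)
    stop("model output has length ", length(fw$out),
         "; Grad-CAM needs a scalar output - select an output index first")
  spatial <- which(vapply(fw$acts, function(a) length(dim(a)) == 3, logical(1)))
  if (is.null(layer)) {
    if (length(spatial) == 0) stop("model has no spatial layer")
    layer <- max(spatial)
  }
  if (!(layer %in% seq_along(model$layers)) || !(layer %in% spatial))
    stop("layer ", layer, " does not produce a spatial feature volume")
  bk <- nn_backward(model, fw$caches, 1)
  A <- fw$acts[[layer]]
  dA <- bk$bnd[[layer]]
  w <- colMeans(matrix(dA, prod(dim(dA)[1:2]), dim(dA)[3]))
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) cam <- cam + w[k] * A[, , k]
  cam <- pmax(cam, 0)
  cam <- resize_bilinear(cam, dim(x)[1], dim(x)[2])
  cam <- pmax(cam, 0)   # bilinear cannot undershoot, but keep the contract explicit
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  structure(list(values = cam, source_layer = layer), class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat("<heat_map>", nrow(x$values), "x", ncol(x$values),
      "from layer", x$source_layer, "- max", format(max(x$values)), "\n")
  invisible(x)
}

jet_colormap <- function(v) {
  cbind(clamp01(1.5 - abs(4 * v - 3)),
        clamp01(1.5 - abs(4 * v - 2)),
        clamp01(1.5 - abs(4 * v - 1)))
}

#' Render a heat-map overlay
#'
#' Alpha-blends a jet-colorized heat map onto the grayscale image; blend
#' weight at each pixel is `alpha` times the heat value, so zero-heat
#' pixels show the unmodified radiograph. Region boxes are drawn as 1-pixel
#' outlines: carpal in green, metacarpus and phalanx in red (unlabeled
#' boxes in yellow).
#'
#' @param heatmap a `heat_map` (or plain matrix in `[0,1]`).
#' @param image grayscale matrix, same shape.
#' @param boxes optional list of [region_box()] objects to outline.
#' @param file optional PNG path to write.
#' @param alpha maximum blend weight (default 0.5).
#' @return `(h, w, 3)` RGB array in `[0,1]`, invisibly if `file` is given.
#' @export
overlay <- function(heatmap, image, boxes = NULL, file = NULL, alpha = 0.5) {
  h <- if (inherits(heatmap, "heat_map")) heatmap$values else heatmap
  stopifnot(all(dim(h) == dim(image)))
  col <- jet_colormap(as.vector(h))
  w <- alpha * as.vector(h)
  rgb <- vapply(1:3, function(ch) (1 - w) * as.vector(image) + w * col[, ch],
                numeric(length(image)))
  out <- array(rgb, c(dim(image), 3L))
  box_cols <- c(carpal = "green", metacarpus_phalanx = "red", unlabeled = "yellow")
  for (b in boxes) {
    rgbcol <- col2rgb(box_cols[[b$role]]) / 255
    rs <- b$row_start + 1; re <- b$row_end; cs <- b$col_start + 1; ce <- b$col_end
    for (ch in 1:3) {
      out[c(rs, re), cs:ce, ch] <- rgbcol[ch]
      out[rs:re, c(cs, ce), ch] <- rgbcol[ch]
    }
  }
  if (!is.null(file)) {
    png::writePNG(clamp01(out), file)
    return(invisible(out))
  }
  out
}

#' Export a heat map as a portable array file
#'
#' Writes the heat-map values as a plain-text CSV grid (row-major,
#' no header) so any array library can re-load it.
#'
#' @param heatmap a `heat_map`.
#' @param path output path.
#' @export
export_heatmap <- function(heatmap, path) {
  utils::write.table(heatmap$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
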