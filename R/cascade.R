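# Cascaded critical-bone-region discovery: locate the heat map's peak
# attention area, crop it, mask it with a black rectangle, and re-run
# saliency so attention shifts to the next most informative region.
# All box coordinates are 0-based, half-open [start, end), row-major.

#' Axis-aligned region box
#'
#' Coordinates are 0-based and half-open on both axes, so a box covering
#' image rows 10..19 (1-based) is `row_start = 9, row_end = 19`.
#'
#' @param row_start,row_end,col_start,col_end integer bounds,
#'   `start < end`.
#' @param role one of `"carpal"`, `"metacarpus_phalanx"`, `"unlabeled"`.
#' @param rank integer discovery order (1 = first found), or `NA`.
#' @return an object of class `region_box`.
#' @export
region_box <- function(row_start, row_end, col_start, col_end,
                       role = "unlabeled", rank = NA_integer_) {
  role <- match.arg(role, c("carpal", "metacarpus_phalanx", "unlabeled"))
  b <- list(row_start = as.integer(row_start), row_end = as.integer(row_end),
            col_start = as.integer(col_start), col_end = as.integer(col_end),
            role = role, rank = as.integer(rank))
  if (b$row_start >= b$row_end || b$col_start >= b$col_end)
    stop("degenerate box: start must be < end on both axes")
  if (b$row_start < 0 || b$col_start < 0)
    stop("box coordinates must be non-negative")
  structure(b, class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("<region_box %s rank=%s rows [%d,%d) cols [%d,%d)>\n",
              x$role, x$rank, x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

box_area <- function(b) (b$row_end - b$row_start) * (b$col_end - b$col_start)

box_intersection_area <- function(a, b) {
  max(0, min(a$row_end, b$row_end) - max(a$row_start, b$row_start)) *
    max(0, min(a$col_end, b$col_end) - max(a$col_start, b$col_start))
}

check_box_in_image <- function(box, image) {
  if (box$row_end > nrow(image) || box$col_end > ncol(image))
    stop("box [", box$row_start, ",", box$row_end, ")x[", box$col_start, ",",
         box$col_end, ") exceeds image bounds ", nrow(image), "x", ncol(image))
  invisible(TRUE)
}

# grow [s, e) within [0, n) to at least `size`, expanding symmetrically and
# shifting at the borders.
ensure_min_extent <- function(s, e, size, n) {
  size <- min(size, n)
  d <- size - (e - s)
  if (d > 0) {
    s <- s - floor(d / 2); e <- e + ceiling(d / 2)
    if (s < 0) { e <- e - s; s <- 0 }
    if (e > n) { s <- s - (e - n); e <- n }
    s <- max(s, 0)
  }
  c(s, e)
}

#' Locate the peak attention region of a heat map
#'
#' Finds the global maximum pixel (ties broken to the first maximum in
#' row-major scan order), takes the 8-connected component of pixels at or
#' above `threshold_frac` times the maximum that contains it, and returns
#' that component's bounding box expanded by `pad_frac` of its side length
#' on each side, clipped to the image, with each side grown to at least
#' `min_size` pixels.
#'
#' @param heatmap a `heat_map` (from [grad_cam()]) or plain non-negative
#'   matrix.
#' @param threshold_frac fraction of the maximum defining the peak
#'   component, in (0, 1). Default 0.5.
#' @param min_size minimum box side length in pixels. Default 32 (sized to
#'   the 300-pixel working resolution; scale it with the image).
#' @param pad_frac fractional padding per side. Default 0.10.
#' @return a [region_box()] (role `"unlabeled"`).
#' @export
locate_peak_region <- function(heatmap, threshold_frac = 0.5, min_size = 32L,
                               pad_frac = 0.10) {
  v <- if (inherits(heatmap, "heat_map")) heatmap$values else heatmap
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  mx <- max(v)
  if (mx <= 0)
    stop(structure(class = c("osteoage_no_salient_region", "error", "condition"),
                   list(message = "heat map is identically zero: no salient region",
                        call = sys.call())))
  # row-major tie-break: scan the transpose column-major
  i <- which.max(t(v))
  r <- (i - 1) %/% ncol(v) + 1
  c <- (i - 1) %% ncol(v) + 1
  comp <- cpp_component_at(v >= threshold_frac * mx, r - 1L, c - 1L)
  rows <- range(which(rowSums(comp) > 0))
  cols <- range(which(colSums(comp) > 0))
  rs <- rows[1] - 1; re <- rows[2]; cs <- cols[1] - 1; ce <- cols[2]
  pr <- round(pad_frac * (re - rs)); pc <- round(pad_frac * (ce - cs))
  rs <- max(0, rs - pr); re <- min(nrow(v), re + pr)
  cs <- max(0, cs - pc); ce <- min(ncol(v), ce + pc)
  rr <- ensure_min_extent(rs, re, min_size, nrow(v))
  cc <- ensure_min_extent(cs, ce, min_size, ncol(v))
  region_box(rr[1], rr[2], cc[1], cc[2])
}

#' Mask a region with a constant fill
#'
#' Returns a copy of the image with every pixel inside the box set to
#' `fill` (default 0, a black rectangle); all other pixels are untouched.
#'
#' @param image numeric matrix.
#' @param box a [region_box()] within the image bounds.
#' @param fill fill intensity.
#' @return masked copy of `image`.
#' @export
mask_region <- function(image, box, fill = 0) {
  check_box_in_image(box, image)
  image[(box$row_start + 1):box$row_end, (box$col_start + 1):box$col_end] <- fill
  image
}

#' Crop a region, optionally resampling
#'
#' Extracts the box from the image and, if `out_size` is given, resamples
#' it to that size with bilinear interpolation.
#'
#' @inheritParams mask_region
#' @param out_size optional `(h, w)` output size.
#' @return numeric matrix.
#' @export
crop_region <- function(image, box, out_size = NULL) {
  check_box_in_image(box, image)
  sub <- image[(box$row_start + 1):box$row_end,
               (box$col_start + 1):box$col_end, drop = FALSE]
  if (!is.null(out_size)) sub <- resize_bilinear(sub, out_size[1], out_size[2])
  sub
}

#' Fixed-size crop centered on a region
#'
#' Extracts a `size[1] x size[2]` window centered on the box center,
#' shifted (not shrunk) where it would cross the image border, so every
#' crop keeps the native pixel scale — no resampling. Preferred over
#' [crop_region()] with `out_size` when the downstream features are
#' sensitive to magnification (texture grain, trabecular detail).
#'
#' @inheritParams mask_region
#' @param size `(h, w)` window size.
#' @return numeric matrix of dimension `size`.
#' @export
crop_fixed <- function(image, box, size = c(32L, 32L)) {
  check_box_in_image(box, image)
  ctr <- c((box$row_start + box$row_end) / 2, (box$col_start + box$col_end) / 2)
  rs <- round(ctr[1] - size[1] / 2); cs <- round(ctr[2] - size[2] / 2)
  rs <- min(max(rs, 0), nrow(image) - size[1])
  cs <- min(max(cs, 0), ncol(image) - size[2])
  image[rs + seq_len(size[1]), cs + seq_len(size[2]), drop = FALSE]
}

# Shrink `b` so it no longer intersects `other`, cutting on the single side
# that loses the least area. Returns NULL if nothing usable remains.
clip_box_against <- function(b, other) {
  if (box_intersection_area(b, other) == 0) return(b)
  cand <- list()
  if (other$row_start > b$row_start)          # keep the part above
    cand <- c(cand, list(c(b$row_start, min(b$row_end, other$row_start),
                           b$col_start, b$col_end)))
  if (other$row_end < b$row_end)              # below
    cand <- c(cand, list(c(max(b$row_start, other$row_end), b$row_end,
                           b$col_start, b$col_end)))
  if (other$col_start > b$col_start)          # left
    cand <- c(cand, list(c(b$row_start, b$row_end,
                           b$col_start, min(b$col_end, other$col_start))))
  if (other$col_end < b$col_end)              # right
    cand <- c(cand, list(c(b$row_start, b$row_end,
                           max(b$col_start, other$col_end), b$col_end)))
  cand <- Filter(function(x) x[2] > x[1] && x[4] > x[3], cand)
  if (length(cand) == 0) return(NULL)
  areas <- vapply(cand, function(x) (x[2] - x[1]) * (x[4] - x[3]), numeric(1))
  k <- cand[[which.max(areas)]]
  region_box(k[1], k[2], k[3], k[4], role = b$role, rank = b$rank)
}

#' Cascaded critical-region extraction
#'
#' Iteratively discovers salient regions: at each step a Grad-CAM heat map
#' is computed on the current image, its peak attention region is located
#' and cropped, and the region is masked with a black rectangle before the
#' next step, so saliency shifts to the next most informative area. Later
#' boxes are clipped against earlier ones so all box interiors are
#' pairwise disjoint. If a step yields an all-zero heat map the result is
#' returned with the regions found so far and flagged partial.
#'
#' @param model scalar-output `osteo_net` used for saliency.
#' @param image grayscale matrix in `[0,1]`.
#' @param n_regions number of regions to extract (default 2).
#' @param roles role labels by discovery rank; the default mirrors the
#'   clinically observed order (carpal first, then metacarpus and
#'   phalanx).
#' @param threshold_frac,pad_frac,min_size passed to
#'   [locate_peak_region()]; `min_size` defaults to 32/300 of the shorter
#'   image side.
#' @param crop_size `(h, w)` of the output crops (default: native box
#'   size).
#' @param layer Grad-CAM source layer (default: last spatial layer).
#' @return a `cascade_result`: lists `boxes`, `crops`, `heatmaps`,
#'   `masked_images` of equal length, plus `partial` flag and the
#'   parameters used.
#' @export
extract_cascade <- function(model, image, n_regions = 2L,
                            roles = c("carpal", "metacarpus_phalanx"),
                            threshold_frac = 0.5, pad_frac = 0.10,
                            min_size = NULL, crop_size = NULL, layer = NULL) {
  stopifnot(n_regions >= 1)
  if (is.null(min_size))
    min_size <- max(1L, as.integer(round(32 / 300 * min(dim(image)))))
  roles <- rep_len(c(roles, rep("unlabeled", n_regions)), n_regions)
  boxes <- crops <- heatmaps <- masked <- list()
  cur <- image
  partial <- FALSE
  for (i in seq_len(n_regions)) {
    hm <- grad_cam(model, cur, layer = layer)
    box <- tryCatch(
      locate_peak_region(hm, threshold_frac = threshold_frac,
                         min_size = min_size, pad_frac = pad_frac),
      osteoage_no_salient_region = function(e) NULL)
    if (!is.null(box)) {
      box$role <- roles[i]
      box$rank <- i
      for (prev in boxes) {
        box <- clip_box_against(box, prev)
        if (is.null(box)) break
      }
    }
    if (is.null(box)) { partial <- TRUE; break }
    heatmaps[[i]] <- hm
    boxes[[i]] <- box
    crops[[i]] <- crop_region(cur, box, out_size = crop_size)
    cur <- mask_region(cur, box, fill = 0)
    masked[[i]] <- cur
  }
  structure(list(boxes = boxes, crops = crops, heatmaps = heatmaps,
                 masked_images = masked, partial = partial,
                 params = list(n_regions = n_regions, roles = roles,
                               threshold_frac = threshold_frac,
                               pad_frac = pad_frac, min_size = min_size,
                               crop_size = crop_size,
                               coordinates = coord_convention())),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>", length(x$boxes), "region(s)",
      if (x$partial) "(partial)" else "", "\n")
  for (b in x$boxes) print(b)
  invisible(x)
}
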