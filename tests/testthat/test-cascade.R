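test_that("locate_peak_region handles point, uniform and two-blob maps", {
  # single nonzero pixel
  v <- matrix(0, 12, 12); v[5, 8] <- 1
  b <- locate_peak_region(v, min_size = 1, pad_frac = 0)
  expect_equal(c(b$row_start, b$row_end, b$col_start, b$col_end), c(4, 5, 7, 8))
  # uniform map: tie broken to first pixel row-major; component = whole image
  u <- matrix(0.7, 9, 11)
  bu <- locate_peak_region(u, min_size = 1, pad_frac = 0)
  expect_equal(c(bu$row_start, bu$row_end, bu$col_start, bu$col_end),
               c(0, 9, 0, 11))
  # two Gaussian blobs, peaks 1.0 and 0.6: box covers only the brighter one
  g <- function(h, w, c1, c2, s, a) {
    a * exp(-(outer((seq_len(h) - c1)^2, (seq_len(w) - c2)^2, "+")) / (2 * s^2))
  }
  v2 <- g(40, 40, 12, 12, 3, 1.0) + g(40, 40, 30, 30, 3, 0.6)
  b2 <- locate_peak_region(v2, threshold_frac = 0.5, min_size = 1, pad_frac = 0)
  comp <- oracle_peak_component(v2, 0.5)
  rows <- range(which(rowSums(comp) > 0)); cols <- range(which(colSums(comp) > 0))
  expect_equal(c(b2$row_start, b2$row_end, b2$col_start, b2$col_end),
               c(rows[1] - 1, rows[2], cols[1] - 1, cols[2]))
  expect_true(b2$row_end <= 22 && b2$col_end <= 22)  # away from the dim blob
})

test_that("row-major tie-break picks the first maximal pixel", {
  v <- matrix(0, 6, 6)
  v[3, 5] <- v[4, 2] <- 1        # row-major order sees (3,5) first
  b <- locate_peak_region(v, min_size = 1, pad_frac = 0)
  expect_equal(c(b$row_start, b$col_start), c(2, 4))
})

test_that("mask_region changes exactly the box pixels and is idempotent", {
  set.seed(11)
  img <- matrix(runif(1e4, min = 0.1), 100, 100)
  b <- region_box(10, 20, 30, 50)
  m <- mask_region(img, b)
  expect_equal(sum(m != img), 200)          # 10 x 20 pixels
  expect_equal(sum(m == 0), 200)
  out <- m; out[11:20, 31:50] <- img[11:20, 31:50]
  expect_identical(out, img)                # complement untouched, pixelwise
  expect_identical(mask_region(m, b), m)    # idempotent
  # full-image box -> all zeros; custom fill honored
  expect_true(all(mask_region(img, region_box(0, 100, 0, 100)) == 0))
  expect_true(all(mask_region(img, b, fill = 0.5)[11:20, 31:50] == 0.5))
  expect_error(mask_region(img, region_box(95, 105, 0, 10)), "bounds")
})

test_that("crop_region is exact: identity, constants and bilinear arithmetic", {
  set.seed(12)
  img <- matrix(runif(64), 8, 8)
  full <- region_box(0, 8, 0, 8)
  expect_equal(crop_region(img, full, out_size = c(8, 8)), img,
               tolerance = 1e-12)
  expect_identical(crop_region(img, region_box(2, 5, 1, 4)), img[3:5, 2:4])
  cst <- crop_region(matrix(0.4, 10, 10), region_box(1, 5, 1, 5),
                     out_size = c(7, 7))
  expect_true(all(abs(cst - 0.4) < 1e-12))
  # 2x2 -> 4x4, half-pixel-center convention, by hand:
  # source coords per output index: -0.25, 0.25, 0.75, 1.25 -> clamped
  m <- matrix(c(1, 3, 2, 4), 2, 2)   # [1 2; 3 4]
  up <- crop_region(m, region_box(0, 2, 0, 2), out_size = c(4, 4))
  w <- c(0, 0.25, 0.75, 1)
  expected <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    r <- w[i]; c <- w[j]
    (1 - r) * ((1 - c) * 1 + c * 2) + r * ((1 - c) * 3 + c * 4)
  }))
  expect_equal(up, expected, tolerance = 1e-12)
})

test_that("crop_fixed keeps native scale and shifts at borders", {
  set.seed(13)
  img <- matrix(runif(64 * 64), 64, 64)
  b <- region_box(20, 30, 24, 36)
  cr <- crop_fixed(img, b, c(16, 16))
  expect_equal(dim(cr), c(16, 16))
  expect_identical(cr, img[18:33, 23:38])   # centered, no resampling
  bc <- region_box(0, 6, 0, 6)              # corner box: window shifts inside
  expect_identical(crop_fixed(img, bc, c(16, 16)), img[1:16, 1:16])
})

test_that("cascade with one region equals a single locate + crop", {
  p <- synth_params(n_samples = 2, seed = 3)
  ds <- generate_dataset(p)
  toy <- toy_saliency_model(p)
  res <- extract_cascade(toy, ds[[1]]$image, n_regions = 1)
  expect_length(res$boxes, 1)
  hm <- grad_cam(toy, ds[[1]]$image)
  b <- locate_peak_region(hm, min_size = res$params$min_size)
  expect_equal(unclass(res$boxes[[1]])[1:4], unclass(b)[1:4])
  expect_identical(res$crops[[1]], crop_region(ds[[1]]$image, b))
  expect_equal(res$boxes[[1]]$role, "carpal")
  expect_equal(res$boxes[[1]]$rank, 1L)
})

test_that("cascade results are deterministic and interior-disjoint", {
  p <- synth_params(n_samples = 5, seed = 17)
  ds <- generate_dataset(p)
  toy <- toy_saliency_model(p)
  for (s in ds) {
    r1 <- extract_cascade(toy, s$image)
    r2 <- extract_cascade(toy, s$image)
    expect_identical(r1, r2)                      # bit-identical
    expect_length(r1$boxes, 2)
    expect_equal(osteoage:::box_intersection_area(r1$boxes[[1]],
                                                  r1$boxes[[2]]), 0)
    # serialized record is byte-identical across runs
    f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
    write_region_record(r1, s$id, f1, seed = 17)
    write_region_record(r2, s$id, f2, seed = 17)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("an all-black image yields a partial result with zero regions", {
  p <- synth_params(n_samples = 2, seed = 3)
  toy <- toy_saliency_model(p)
  res <- extract_cascade(toy, matrix(0, 64, 64))
  expect_true(res$partial)
  expect_length(res$boxes, 0)
})

test_that("cascade recovers the two planted regions on generator images", {
  p <- synth_params(n_samples = 10, seed = 23)
  ds <- generate_dataset(p)
  toy <- toy_saliency_model(p)
  hits <- vapply(ds, function(s) {
    res <- extract_cascade(toy, s$image)
    if (length(res$boxes) < 2) return(c(FALSE, FALSE))
    vapply(1:2, function(k) {
      tb <- s$truth_boxes[[k]]
      box_contains_point(res$boxes[[k]],
                         (tb$row_start + tb$row_end) / 2,
                         (tb$col_start + tb$col_end) / 2)
    }, logical(1))
  }, logical(2))
  expect_true(all(hits))
})

test_that("region boxes validate their geometry", {
  expect_error(region_box(5, 5, 0, 2), "degenerate")
  expect_error(region_box(-1, 5, 0, 2), "non-negative")
  expect_error(region_box(0, 2, 0, 2, role = "elbow"))
})
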