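# Readers and writers: PNG images, RSNA-dialect label tables, region
# records and model checkpoints. All serialized coordinates carry the
# "0-based, half-open, row-major" convention string.

#' Read a grayscale radiograph
#'
#' Reads an 8- or 16-bit PNG; RGB images are collapsed to luminance
#' (Rec. 709 weights). Intensities are returned as reals in `[0, 1]`; the
#' original bit depth is recorded in the `"bit_depth"` attribute.
#'
#' @param path PNG path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image '", path, "': file not found")
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot read image '", path, "': ",
                                           conditionMessage(e)))
  depth <- tryCatch({
    hdr <- readBin(path, "raw", n = 25)
    as.integer(hdr[25])
  }, error = function(e) NA_integer_)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img <- img[, , 1]
  }
  structure(img, bit_depth = depth)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param image matrix in `[0, 1]` (clamped on write).
#' @param path output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp01(unclass(image)), path)
  invisible(path)
}

parse_male <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read an RSNA-dialect labels table
#'
#' Expects a CSV whose header contains (case-insensitively) `id`,
#' `boneage` (months) and `male` (true/false/1/0). Validates uniqueness of
#' ids and finite non-negative ages; errors name the offending rows.
#'
#' @param path CSV path.
#' @return data frame with columns `id` (character), `boneage` (numeric),
#'   `male` (logical).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file '", path, "' not found")
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "boneage", "male")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("labels file is missing column(s): ", paste(miss, collapse = ", "))
  id <- as.character(df$id)
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate id(s) in labels: ", paste(dup, collapse = ", "))
  boneage <- suppressWarnings(as.numeric(df$boneage))
  bad <- which(!is.finite(boneage) | boneage < 0)
  if (length(bad))
    stop("unparsable or negative boneage at row(s): ",
         paste(bad, collapse = ", "))
  male <- parse_male(df$male)
  badm <- which(is.na(male))
  if (length(badm))
    stop("unparsable male flag at row(s): ", paste(badm, collapse = ", "))
  data.frame(id = id, boneage = boneage, male = male,
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file whose payload holds every parameter
#' array together with a JSON configuration block (model class, backbone
#' and dimension configuration, coordinate convention, package version,
#' and any extra metadata supplied).
#'
#' @param model a `fusion_model` or `osteo_net`.
#' @param path checkpoint path.
#' @param extra named list merged into the config block.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model with the config block in attribute `"config"`.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  cfg <- c(list(model_class = class(model)[1],
                package_version = as.character(packageVersion("osteoage")),
                coordinates = coord_convention()),
           if (inherits(model, "fusion_model"))
             list(use_cbam = model$cfg$use_cbam,
                  use_gender = model$cfg$use_gender,
                  backbones = c(model$cfg$cfg_a$backbone_name,
                                model$cfg$cfg_b$backbone_name),
                  input_size = model$cfg$cfg_a$input_size),
           extra)
  saveRDS(list(config_json = jsonlite::toJSON(cfg, auto_unbox = TRUE),
               model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint '", path, "' not found")
  ck <- readRDS(path)
  structure(ck$model, config = jsonlite::fromJSON(ck$config_json))
}

#' Write / read a region record
#'
#' Serializes a [extract_cascade()] result for one image as JSON: boxes
#' with roles and ranks, the cascade parameters, the coordinate
#' convention, the package version, and the seed if supplied. The record
#' round-trips losslessly.
#'
#' @param result a `cascade_result`.
#' @param id image identifier.
#' @param path output JSON path.
#' @param seed optional seed to embed.
#' @export
write_region_record <- function(result, id, path, seed = NULL) {
  rec <- list(id = id,
              coordinates = coord_convention(),
              package_version = as.character(packageVersion("osteoage")),
              seed = seed,
              partial = result$partial,
              params = result$params[c("n_regions", "threshold_frac",
                                       "pad_frac", "min_size")],
              boxes = lapply(result$boxes, unclass))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_region_record
#' @export
read_region_record <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rec$boxes <- lapply(rec$boxes, function(b)
    region_box(b$row_start, b$row_end, b$col_start, b$col_end,
               role = b$role, rank = b$rank))
  rec
}
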