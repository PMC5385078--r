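#' Read a canopy image
#'
#' Accepts lossless PNG or TIFF. JPEG is refused: lossy compression
#' shifts hues, which corrupts the color features this pipeline relies
#' on (and no JPEG decoder is bundled). Alpha channels are dropped and
#' grayscale images replicated to three channels.
#'
#' @param path image file path.
#' @return numeric `h x w x 3` array in `[0, 1]`.
#' @export
read_canopy_image <- function(path) {
  if (!file.exists(path)) {
    idc_error("idc_invalid_input", sprintf("image not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        idc_error("idc_invalid_input", "the tiff package is required for TIFF input")
      }
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = idc_error("idc_invalid_input",
      "JPEG input is refused: lossy compression distorts hue; use PNG or TIFF"),
    idc_error("idc_invalid_input",
              sprintf("unsupported image format: .%s (use PNG or TIFF)", ext))
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image numeric `h x w x 3` array in `[0, 1]`.
#' @param path output path.
#' @export
write_canopy_image <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image, path)
  invisible(path)
}

# Run-length encode a logical matrix (column-major), compactly.
rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), first = r$values[1], lengths = r$lengths)
}

rle_decode_mask <- function(enc) {
  vals <- rep(c(enc$first, !enc$first), length.out = length(enc$lengths))
  matrix(inverse.rle(list(lengths = enc$lengths, values = vals)),
         enc$dim[1], enc$dim[2])
}

#' Write a segmentation mask
#'
#' As a 0/255 grayscale PNG and/or a run-length-encoded JSON sidecar.
#'
#' @param mask an `idc_mask` or logical matrix.
#' @param png_path,json_path output paths (`NULL` to skip).
#' @export
write_mask <- function(mask, png_path = NULL, json_path = NULL) {
  m <- if (inherits(mask, "idc_mask")) mask$mask else mask
  stopifnot(is.logical(m), is.matrix(m))
  if (!is.null(png_path)) {
    png::writePNG(m * 1, png_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(rle_encode_mask(m), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(mask)
}

#' Read a run-length-encoded mask JSON
#'
#' @param json_path path written by [write_mask()].
#' @return logical matrix.
#' @export
read_mask <- function(json_path) {
  enc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  rle_decode_mask(enc)
}

#' Write a synthetic sample to disk
#'
#' The image goes to `<dir>/<id>.png` and the ground truth (planted
#' fractions, rating, metadata, chart drift and the RLE-encoded truth
#' mask) to a JSON sidecar `<dir>/<id>.json`.
#'
#' @param sample an `idc_sample` from [generate_canopy_image()].
#' @param dir output directory (created if missing).
#' @param id file stem.
#' @return named character vector of the two paths.
#' @export
write_sample <- function(sample, dir, id) {
  stopifnot(inherits(sample, "idc_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(id, ".png"))
  json_path <- file.path(dir, paste0(id, ".json"))
  png::writePNG(sample$image, img_path)
  jsonlite::write_json(list(
    planted_yellow_pct = sample$planted_yellow_pct,
    planted_brown_pct = sample$planted_brown_pct,
    rating = sample$rating,
    chart_drift = sample$chart_drift,
    metadata = sample$metadata,
    truth_mask = rle_encode_mask(sample$truth_mask)
  ), json_path, auto_unbox = TRUE, digits = NA)
  c(image = img_path, truth = json_path)
}

#' Export a pixel label map as an indexed PNG
#'
#' Grayscale PNG with levels 0 (background), 1/3 (green), 2/3 (yellow)
#' and 1 (brown), i.e. the label code divided by 3.
#'
#' @param labels an `idc_labels` matrix from [classify_canopy_pixels()].
#' @param path output PNG path.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "idc_labels"))
  png::writePNG(unclass(labels) / 3, path)
  invisible(path)
}

#' Read / write labeled feature tables as CSV
#'
#' @param table data.frame with `yellow_pct`, `brown_pct` and optionally
#'   `rating` (plus any id columns).
#' @param path CSV path.
#' @return `read_feature_table` returns the data.frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("yellow_pct", "brown_pct") %in% names(tab))) {
    idc_error("idc_invalid_input",
              "feature table needs yellow_pct and brown_pct columns")
  }
  tab
}

#' Read a segmentation config from YAML or JSON
#'
#' Recognized keys: `sat_min`, `fg_hue_window`, `connectivity` (missing
#' keys keep their defaults).
#'
#' @param path config file path (.yaml/.yml/.json).
#' @return an `idc_seg_config`.
#' @export
read_seg_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- seg_config()
  seg_config(
    sat_min = if (is.null(x$sat_min)) defaults$sat_min else x$sat_min,
    fg_hue_window = if (is.null(x$fg_hue_window)) defaults$fg_hue_window
                    else unlist(x$fg_hue_window),
    connectivity = if (is.null(x$connectivity)) defaults$connectivity
                   else x$connectivity)
}
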