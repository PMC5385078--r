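#' Segmentation configuration
#'
#' Thresholds used to separate the plant canopy (foreground) from the soil
#' background. A pixel is kept when its saturation is at least `sat_min`
#' AND its hue falls inside `fg_hue_window`. The soil background is mostly
#' gray (low saturation) and carries hues that are neither green nor brown,
#' so the two arms of the threshold are complementary.
#'
#' The default window spans brown through green, `[21, 140]` degrees, and
#' the default saturation floor is 0.15 (on the 0--1 saturation scale).
#' Both are data-dependent constants that should be tuned to the imaging
#' protocol at hand.
#'
#' @param sat_min minimum saturation (fraction in `[0, 1]`) for foreground.
#' @param fg_hue_window length-2 numeric, lower and upper hue bound in
#'   degrees, both in `[0, 360)`, lower <= upper.
#' @param connectivity pixel adjacency for blob cleanup: 4 or 8.
#' @return an object of class `idc_seg_config`.
#' @export
seg_config <- function(sat_min = 0.15, fg_hue_window = c(21, 140),
                       connectivity = 8) {
  stopifnot(is.numeric(sat_min), length(sat_min) == 1L,
            sat_min >= 0, sat_min <= 1)
  stopifnot(is.numeric(fg_hue_window), length(fg_hue_window) == 2L,
            fg_hue_window[1] <= fg_hue_window[2],
            fg_hue_window[1] >= 0, fg_hue_window[2] < 360)
  if (!connectivity %in% c(4, 8)) {
    idc_error("idc_invalid_input", "connectivity must be 4 or 8")
  }
  structure(list(sat_min = sat_min, fg_hue_window = fg_hue_window,
                 connectivity = as.integer(connectivity)),
            class = "idc_seg_config")
}

#' Convert an RGB raster to HSV
#'
#' Standard RGB to HSV conversion with hue expressed in degrees in
#' `[0, 360)` (red at 0 degrees) and saturation/value as fractions in
#' `[0, 1]`.
#'
#' @param image numeric `h x w x 3` array with intensities in `[0, 1]`.
#' @return an object of class `idc_hsv`: list of matrices `h` (degrees),
#'   `s`, `v`.
#' @export
to_hsv <- function(image) {
  assert_rgb_image(image)
  d <- dim(image)[1:2]
  m <- grDevices::rgb2hsv(
    r = as.vector(image[, , 1]),
    g = as.vector(image[, , 2]),
    b = as.vector(image[, , 3]),
    maxColorValue = 1
  )
  structure(list(
    h = matrix((m[1, ] * 360) %% 360, d[1], d[2]),
    s = matrix(m[2, ], d[1], d[2]),
    v = matrix(m[3, ], d[1], d[2])
  ), class = "idc_hsv")
}

# Inverse of to_hsv; returns an 8-bit-quantized RGB array.
hsv_to_rgb <- function(hsv) {
  h <- (as.vector(hsv$h) %% 360) / 360
  cols <- grDevices::hsv(h, pmin(pmax(as.vector(hsv$s), 0), 1),
                         pmin(pmax(as.vector(hsv$v), 0), 1))
  m <- grDevices::col2rgb(cols) / 255
  d <- dim(hsv$h)
  array(c(m[1, ], m[2, ], m[3, ]), dim = c(d[1], d[2], 3))
}

#' Threshold foreground pixels by saturation and hue
#'
#' @param hsv an `idc_hsv` image (see [to_hsv()]).
#' @param config an `idc_seg_config` (see [seg_config()]).
#' @return logical matrix, `TRUE` where the pixel passes both thresholds.
#' @export
threshold_foreground <- function(hsv, config = seg_config()) {
  stopifnot(inherits(hsv, "idc_hsv"), inherits(config, "idc_seg_config"))
  w <- config$fg_hue_window
  hsv$s >= config$sat_min & hsv$h >= w[1] & hsv$h <= w[2]
}

#' Connected-component labeling
#'
#' Labels maximal sets of mutually adjacent foreground pixels. Labels are
#' contiguous from 1 in raster-scan order, so the output is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return list with `labels` (integer matrix, 0 = background) and `sizes`
#'   (integer vector; `sizes[k]` is the pixel count of component `k`).
#' @export
connected_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!connectivity %in% c(4, 8)) {
    idc_error("idc_invalid_input", "connectivity must be 4 or 8")
  }
  mask[is.na(mask)] <- FALSE
  .cc_label(mask, as.integer(connectivity))
}

#' Keep only the largest connected component
#'
#' Under the standard imaging protocol the plant is centered and is the
#' largest blob in the thresholded image, so every smaller component
#' (debris, chart patches, soil speckle) is discarded. When two components
#' tie for the largest size, the one whose centroid is nearest the image
#' center is kept, again because the protocol centers the plant.
#'
#' @param mask logical matrix of foreground pixels.
#' @param connectivity 4 or 8.
#' @param image_center numeric length-2 `(row, col)`; defaults to the
#'   geometric center of the raster.
#' @return an object of class `idc_mask`: list with `mask` (logical
#'   matrix, a single connected component) and `canopy_pixel_count`.
#' @export
largest_component <- function(mask, connectivity = 8, image_center = NULL) {
  cc <- connected_components(mask, connectivity)
  if (length(cc$sizes) == 0L) {
    idc_error("idc_no_canopy", "no foreground pixels: no canopy found")
  }
  best <- which(cc$sizes == max(cc$sizes))
  if (length(best) > 1L) {
    if (is.null(image_center)) {
      image_center <- (dim(mask) + 1) / 2
    }
    d2 <- vapply(best, function(k) {
      idx <- which(cc$labels == k, arr.ind = TRUE)
      sum((colMeans(idx) - image_center)^2)
    }, numeric(1))
    best <- best[which.min(d2)]
  } else {
    best <- best[1]
  }
  keep <- cc$labels == best
  structure(list(mask = keep, canopy_pixel_count = sum(keep)),
            class = "idc_mask")
}

#' Segment the plant canopy from an RGB image
#'
#' Full preprocessing chain: optional color calibration, RGB to HSV
#' conversion, saturation + hue thresholding, and largest-connected-
#' component cleanup.
#'
#' @param image numeric `h x w x 3` RGB array in `[0, 1]`.
#' @param profile an `idc_calibration` profile, or `NULL` for identity.
#' @param config an `idc_seg_config`.
#' @return an `idc_mask` (single connected component).
#' @export
segment_canopy <- function(image, profile = NULL, config = seg_config()) {
  assert_rgb_image(image)
  if (!is.null(profile)) {
    image <- apply_profile(image, profile)
  }
  hsv <- to_hsv(image)
  fg <- threshold_foreground(hsv, config)
  largest_component(fg, config$connectivity)
}
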