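#' Color-chart layout
#'
#' Describes where the calibration patches sit in a chart (or chart-bearing
#' canopy) image and the reference values they should read: a neutral grey
#' level for white balance, and defined hues for the green, brown and
#' yellow patches used to measure hue drift. The defaults match the chart
#' rendered by [generate_canopy_image()].
#'
#' @param patches named list (`grey`, `green`, `brown`, `yellow`) of lists
#'   with integer vectors `rows` and `cols` giving each patch's pixel
#'   region (inclusive ranges).
#' @param ref_hues named numeric: defined hues (degrees) of the chromatic
#'   patches.
#' @param grey_level reference neutral grey intensity in `[0, 1]`.
#' @return an object of class `idc_chart_layout`.
#' @export
chart_layout <- function(patches = default_chart_patches(),
                         ref_hues = c(green = 110, brown = 35, yellow = 65),
                         grey_level = 0.5) {
  stopifnot(all(c("grey", "green", "brown", "yellow") %in% names(patches)))
  stopifnot(all(c("green", "brown", "yellow") %in% names(ref_hues)))
  # regions must be disjoint
  cells <- lapply(patches, function(p) {
    as.vector(outer(p$rows, p$cols, function(r, c) paste(r, c)))
  })
  if (anyDuplicated(unlist(cells))) {
    idc_error("idc_invalid_input", "chart patch regions overlap")
  }
  structure(list(patches = patches, ref_hues = ref_hues,
                 grey_level = grey_level),
            class = "idc_chart_layout")
}

# Patch geometry used by the synthetic generator: four ps x ps patches in
# a row at the top-left corner (grey, green, brown, yellow).
default_chart_patches <- function(ps = 16L, margin = 8L, gap = 4L) {
  ps <- as.integer(ps); margin <- as.integer(margin); gap <- as.integer(gap)
  mk <- function(k) {
    c0 <- margin + (k - 1L) * (ps + gap)
    list(rows = (margin + 1L):(margin + ps), cols = (c0 + 1L):(c0 + ps))
  }
  list(grey = mk(1L), green = mk(2L), brown = mk(3L), yellow = mk(4L))
}

#' Calibration profile
#'
#' Per-channel white-balance gains plus signed hue drifts (degrees)
#' measured at the green, brown and yellow chart patches. The identity
#' profile (gains 1,1,1, drifts 0) leaves any image unchanged.
#'
#' @param gains positive numeric length 3 (R, G, B multipliers).
#' @param drifts named numeric (`green`, `brown`, `yellow`), degrees in
#'   `(-180, 180]`.
#' @param ref_hues anchor hues the drifts were measured at.
#' @param tag free-text provenance tag (e.g. acquisition timestamp).
#' @return an object of class `idc_calibration`.
#' @export
calibration_profile <- function(gains = c(1, 1, 1),
                                drifts = c(green = 0, brown = 0, yellow = 0),
                                ref_hues = c(green = 110, brown = 35,
                                             yellow = 65),
                                tag = "") {
  stopifnot(is.numeric(gains), length(gains) == 3L, all(gains > 0))
  stopifnot(all(c("green", "brown", "yellow") %in% names(drifts)))
  drifts <- drifts[c("green", "brown", "yellow")]
  if (any(drifts <= -180 | drifts > 180)) {
    idc_error("idc_invalid_input", "drifts must lie in (-180, 180]")
  }
  structure(list(gains = as.numeric(gains), drifts = drifts,
                 ref_hues = ref_hues[c("green", "brown", "yellow")],
                 tag = tag),
            class = "idc_calibration")
}

#' @export
print.idc_calibration <- function(x, ...) {
  cat(sprintf(
    "calibration profile: gains (%.3f, %.3f, %.3f); drifts g %+.2f / b %+.2f / y %+.2f deg\n",
    x$gains[1], x$gains[2], x$gains[3],
    x$drifts["green"], x$drifts["brown"], x$drifts["yellow"]))
  invisible(x)
}

#' Read / write a chart layout as YAML or JSON
#'
#' @param layout an `idc_chart_layout`.
#' @param path config path (`.yaml`/`.yml` or `.json`).
#' @return `read_chart_layout` returns an `idc_chart_layout`.
#' @export
write_chart_layout <- function(layout, path) {
  stopifnot(inherits(layout, "idc_chart_layout"))
  x <- list(patches = lapply(layout$patches, function(p) {
    list(rows = range(p$rows), cols = range(p$cols))
  }), ref_hues = as.list(layout$ref_hues), grey_level = layout$grey_level)
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_chart_layout
#' @export
read_chart_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  patches <- lapply(x$patches, function(p) {
    list(rows = p$rows[1]:p$rows[2], cols = p$cols[1]:p$cols[2])
  })
  chart_layout(patches = patches, ref_hues = unlist(x$ref_hues),
               grey_level = x$grey_level)
}

#' Estimate a calibration profile from a chart image
#'
#' White balance comes from the grey patch: each channel gain scales the
#' patch's mean RGB to the common mean (von Kries style), so a neutral
#' grey reads equal channels after correction. Hue drift is the circular
#' difference between each chromatic patch's observed mean hue (after
#' white balance) and its defined reference hue.
#'
#' @param chart_image RGB array containing the chart.
#' @param layout an `idc_chart_layout`.
#' @return an `idc_calibration` profile.
#' @export
estimate_profile <- function(chart_image, layout = chart_layout()) {
  assert_rgb_image(chart_image, "chart_image")
  stopifnot(inherits(layout, "idc_chart_layout"))
  d <- dim(chart_image)
  for (nm in names(layout$patches)) {
    p <- layout$patches[[nm]]
    if (max(p$rows) > d[1] || max(p$cols) > d[2] ||
        min(p$rows) < 1 || min(p$cols) < 1) {
      idc_error("idc_invalid_input",
                sprintf("chart patch '%s' outside image bounds", nm))
    }
  }
  g <- layout$patches$grey
  grey_mean <- vapply(1:3, function(ch) {
    mean(chart_image[g$rows, g$cols, ch])
  }, numeric(1))
  if (any(grey_mean >= 254.5 / 255)) {
    idc_error("idc_calibration_failure",
              "grey patch is clipped (channel at maximum); recapture chart")
  }
  if (any(grey_mean <= 0)) {
    idc_error("idc_calibration_failure", "grey patch is black")
  }
  gains <- mean(grey_mean) / grey_mean

  drifts <- vapply(c("green", "brown", "yellow"), function(nm) {
    p <- layout$patches[[nm]]
    patch <- chart_image[p$rows, p$cols, , drop = FALSE]
    for (ch in 1:3) {
      patch[, , ch] <- pmin(pmax(patch[, , ch] * gains[ch], 0), 1)
    }
    hsv <- to_hsv(patch)
    circ_diff(circ_mean(hsv$h), layout$ref_hues[[nm]])
  }, numeric(1))

  calibration_profile(gains = gains, drifts = drifts,
                      ref_hues = layout$ref_hues)
}

# Piecewise-linear interpolation of the drift over the hue circle,
# anchored at the three reference hues (wraparound-aware).
interp_drift <- function(h, profile) {
  anchors <- (profile$ref_hues + profile$drifts) %% 360  # observed hues
  vals <- as.numeric(profile$drifts)
  ord <- order(anchors)
  a <- as.numeric(anchors[ord]); v <- vals[ord]
  # close the circle: append first anchor + 360
  a_ext <- c(a, a[1] + 360)
  v_ext <- c(v, v[1])
  hh <- h %% 360
  hh <- ifelse(hh < a[1], hh + 360, hh)
  idx <- findInterval(hh, a_ext, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  lo <- a_ext[idx]; hi <- a_ext[idx + 1L]
  w <- ifelse(hi > lo, (hh - lo) / (hi - lo), 0)
  (1 - w) * v_ext[idx] + w * v_ext[idx + 1L]
}

#' Apply a calibration profile to an image
#'
#' Channels are multiplied by the white-balance gains and clipped to
#' `[0, 1]`; hues are then corrected by subtracting the drift, linearly
#' interpolated between the three anchor hues around the hue circle
#' (saturation and value are untouched by the hue remap). The identity
#' profile returns the input bit-for-bit.
#'
#' @param image RGB array in `[0, 1]`.
#' @param profile an `idc_calibration`.
#' @return RGB array, same dimensions, intensities in `[0, 1]`.
#' @export
apply_profile <- function(image, profile) {
  assert_rgb_image(image)
  stopifnot(inherits(profile, "idc_calibration"))
  if (all(profile$gains == 1) && all(profile$drifts == 0)) {
    return(image)
  }
  out <- image
  if (any(profile$gains != 1)) {
    for (ch in 1:3) {
      out[, , ch] <- pmin(pmax(out[, , ch] * profile$gains[ch], 0), 1)
    }
  }
  if (any(profile$drifts != 0)) {
    hsv <- to_hsv(out)
    # drift is measured at the *observed* (drifted) hues, so the
    # correction is indexed by the observed hue of each pixel
    hsv$h <- (hsv$h - interp_drift(hsv$h, profile)) %% 360
    out <- hsv_to_rgb(hsv)
  }
  out
}

#' Read/write calibration profiles as JSON
#'
#' @param profile an `idc_calibration`.
#' @param path file path.
#' @return `read_profile` returns an `idc_calibration`;
#'   `write_profile` returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "idc_calibration"))
  jsonlite::write_json(
    list(gains = profile$gains, drifts = as.list(profile$drifts),
         ref_hues = as.list(profile$ref_hues), tag = profile$tag),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_profile(gains = x$gains, drifts = unlist(x$drifts),
                      ref_hues = unlist(x$ref_hues),
                      tag = if (is.null(x$tag)) "" else x$tag)
}
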