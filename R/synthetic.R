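#' Rating-conditional feature distribution specification
#'
#' Defines, for each severity rating 1--5, the location and spread of the
#' (Y%, B%) feature pair as a bivariate normal truncated to the feasible
#' simplex (Y >= 0, B >= 0, Y + B <= 100), plus the class priors. The
#' defaults emulate a field population: most plants healthy (rating 1
#' dominates the priors); ratings 1--3 concentrated at low brown values;
#' ratings 3--5 sharing a comparable chlorosis level and separated mainly
#' by necrosis, so the rating-5 decision boundary of a trained classifier
#' runs nearly horizontally in the (Y, B) plane, the way expert rating
#' logic works (beyond a necrosis level the plant is rated 5 regardless
#' of yellowing). Locations sit well inside the simplex so truncation
#' bias is negligible. These shapes are a modeling choice of this
#' package, not field-calibrated values.
#'
#' @param means 5 x 2 numeric matrix, row r = mean (Y%, B%) of rating r.
#' @param sds 5 x 2 numeric matrix of positive standard deviations.
#' @param priors numeric length 5, summing to 1.
#' @return an object of class `idc_feature_spec`.
#' @export
feature_spec <- function(
    means = rbind(c(6, 2), c(25, 2), c(48, 4), c(48, 12), c(48, 28)),
    sds = rbind(c(2, 0.8), c(3, 0.8), c(4, 1.2), c(10, 2), c(10, 4)),
    priors = c(0.40, 0.15, 0.15, 0.15, 0.15)) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  stopifnot(all(dim(means) == c(5, 2)), all(dim(sds) == c(5, 2)),
            length(priors) == 5L)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    idc_error("idc_invalid_input",
              "feature spec spreads must be positive (degenerate spec)")
  }
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
    idc_error("idc_invalid_input",
              "priors must be nonnegative and sum to 1")
  }
  structure(list(means = means, sds = sds, priors = priors / sum(priors)),
            class = "idc_feature_spec")
}

#' Ground-truth severity rating from (Y%, B%)
#'
#' Deterministic piecewise-linear rating rule used as the planted ground
#' truth for synthetic data. It encodes the qualitative field logic of
#' the 1--5 visual scale: beyond a fixed necrosis level (`b_necrosis`)
#' the plant is rated 5 regardless of chlorosis; below it, severity
#' increases with a weighted combination of yellowing and browning, so
#' ratings 1--3 are only reachable at low brown values. The numeric
#' thresholds are this package's own convention (no published boundary
#' values exist), and the rule is monotone non-decreasing in both Y and B.
#'
#' @param yellow_pct,brown_pct numeric vectors of canopy-area percentages.
#' @param b_necrosis brown percentage above which the rating is always 5.
#' @return integer vector of ratings in 1--5.
#' @export
bayes_rating <- function(yellow_pct, brown_pct, b_necrosis = 15) {
  y <- yellow_pct; b <- brown_pct
  if (any(!is.finite(y)) || any(!is.finite(b)) ||
      any(y < 0) || any(b < 0) || any(y + b > 100 + 1e-9)) {
    idc_error("idc_invalid_input",
              "(Y, B) must satisfy Y >= 0, B >= 0, Y + B <= 100")
  }
  ifelse(b > b_necrosis, 5L,
  ifelse(y + 2.5 * b > 60, 4L,
  ifelse(y + 2.0 * b > 35, 3L,
  ifelse(y + 1.5 * b > 15, 2L, 1L))))
}

# Truncated-normal draw for one rating class (rejection sampling).
draw_class_features <- function(n, mean, sd) {
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  for (it in 1:1000) {
    m <- length(need)
    if (m == 0L) break
    y <- stats::rnorm(m, mean[1], sd[1])
    b <- stats::rnorm(m, mean[2], sd[2])
    ok <- y >= 0 & b >= 0 & y + b <= 100
    out[need[ok], ] <- cbind(y[ok], b[ok])
    need <- need[!ok]
  }
  if (length(need) > 0L) {
    idc_error("idc_invalid_input",
              "feature spec places almost no mass on the simplex")
  }
  out
}

#' Generate a rating-labeled (Y%, B%) feature table
#'
#' Samples ratings from the class priors and features from the
#' rating-conditional truncated normals of the spec. Reproducible under a
#' fixed seed.
#'
#' @param spec an `idc_feature_spec`.
#' @param n number of rows (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `yellow_pct`, `brown_pct`, `rating`.
#' @export
generate_feature_table <- function(spec = feature_spec(), n, seed = 1) {
  stopifnot(inherits(spec, "idc_feature_spec"), n >= 1)
  with_seed(seed, {
    rating <- sample.int(5L, n, replace = TRUE, prob = spec$priors)
    feat <- matrix(NA_real_, n, 2)
    for (r in 1:5) {
      idx <- which(rating == r)
      if (length(idx) > 0L) {
        feat[idx, ] <- draw_class_features(length(idx), spec$means[r, ],
                                           spec$sds[r, ])
      }
    }
    data.frame(yellow_pct = feat[, 1], brown_pct = feat[, 2],
               rating = as.integer(rating))
  })
}

# Rasterize an ellipse union ("leaflets") centered in the frame. Every
# ellipse contains the image center, so the union is one connected
# component.
canopy_shape <- function(size, n_ellipses = 8L) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  mask <- matrix(FALSE, size, size)
  for (k in seq_len(n_ellipses)) {
    cy <- ctr + stats::runif(1, -size / 14, size / 14)
    cx <- ctr + stats::runif(1, -size / 14, size / 14)
    a <- stats::runif(1, size / 8, size / 5)
    b <- stats::runif(1, size / 8, size / 5)
    th <- stats::runif(1, 0, pi)
    dy <- rows - cy; dx <- cols - cx
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask <- mask | (u / a)^2 + (v / b)^2 <= 1
  }
  mask
}

#' Generate a synthetic canopy image with planted ground truth
#'
#' Renders a centered plant canopy (a union of overlapping ellipses) on a
#' low-saturation soil background, with exact planted fractions of yellow
#' (chlorotic) and brown (necrotic) canopy pixels, optional small debris
#' blobs, and an optional four-patch calibration chart. An optional
#' global hue shift emulates an illumination color cast: it rotates the
#' hue of all chromatic content (canopy, debris and chart), which is what
#' the chart-based drift correction is designed to undo. `chart_drift`
#' additionally offsets the chart patches only.
#'
#' Canopy hues are drawn well inside the brown/yellow/green bands (with a
#' 4 degree guard against 8-bit quantization), so segmenting the image
#' and extracting features recovers the planted fractions to within one
#' pixel of quantization.
#'
#' @param planted_yellow_pct,planted_brown_pct planted canopy-area
#'   percentages; nonnegative with sum <= 100.
#' @param size image side in pixels (square, >= 128).
#' @param n_debris number of soil debris blobs.
#' @param with_chart embed the calibration chart?
#' @param chart_drift extra hue offset (degrees) applied to the chart
#'   patches only.
#' @param hue_shift global hue cast (degrees) applied to all chromatic
#'   content.
#' @param seed integer RNG seed.
#' @param metadata list of identifiers (plot, rep, timepoint ...).
#' @return an object of class `idc_sample`: list with `image` (RGB array),
#'   `truth_mask` (logical matrix), `planted_yellow_pct`,
#'   `planted_brown_pct`, `rating` (from [bayes_rating()]), `chart_drift`
#'   (total hue offset on the chart; 0 when no chart), `chart_layout`
#'   (or `NULL`) and `metadata`.
#' @export
generate_canopy_image <- function(planted_yellow_pct, planted_brown_pct,
                                  size = 256L, n_debris = 3L,
                                  with_chart = FALSE, chart_drift = 0,
                                  hue_shift = 0, seed = 1,
                                  metadata = list()) {
  y <- planted_yellow_pct; b <- planted_brown_pct
  if (!is.finite(y) || !is.finite(b) || y < 0 || b < 0 || y + b > 100) {
    idc_error("idc_invalid_input",
              "planted fractions must be >= 0 with sum <= 100")
  }
  size <- as.integer(size)
  if (size < 128L) {
    idc_error("idc_invalid_input", "size must be at least 128 pixels")
  }
  with_seed(seed, {
    n_px <- size * size
    # soil background: mostly gray-brown (saturation below the default
    # foreground floor), with a minority of more saturated off-window
    # hues so both threshold arms are exercised
    h_bg <- stats::runif(n_px, 20, 60)
    s_bg <- stats::runif(n_px, 0, 0.10)
    v_bg <- stats::runif(n_px, 0.35, 0.65)
    hi_sat <- stats::runif(n_px) < 0.15
    h_bg[hi_sat] <- stats::runif(sum(hi_sat), 300, 350)
    s_bg[hi_sat] <- stats::runif(sum(hi_sat), 0.15, 0.40)
    h <- matrix(h_bg, size, size)
    s <- matrix(s_bg, size, size)
    v <- matrix(v_bg, size, size)
    chromatic <- matrix(FALSE, size, size)  # pixels the global cast hits

    canopy <- canopy_shape(size)
    n_c <- sum(canopy)
    n_b <- floor(b / 100 * n_c + 0.5)
    n_y <- floor(y / 100 * n_c + 0.5)
    if (n_b + n_y > n_c) {
      idc_error("idc_invalid_input",
                "canopy too small to realize the planted fractions")
    }

    # debris: small saturated green/brown discs away from the canopy
    chart_rows <- if (with_chart) 30L else 0L
    chart_cols <- if (with_chart) 95L else 0L
    debris_mask <- matrix(FALSE, size, size)
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    placed <- 0L
    for (tries in seq_len(60L * max(n_debris, 1L))) {
      if (placed >= n_debris) break
      r0 <- stats::runif(1, size / 50, size / 30)
      cy <- stats::runif(1, r0 + 3, size - r0 - 3)
      cx <- stats::runif(1, r0 + 3, size - r0 - 3)
      if (cy - r0 - 3 < chart_rows && cx - r0 - 3 < chart_cols) next
      disc <- (rows - cy)^2 + (cols - cx)^2 <= r0^2
      grown <- (rows - cy)^2 + (cols - cx)^2 <= (r0 + 3)^2
      if (any(grown & canopy)) next
      debris_mask <- debris_mask | disc
      placed <- placed + 1L
    }
    nd <- sum(debris_mask)
    if (nd > 0L) {
      h[debris_mask] <- ifelse(stats::runif(nd) < 0.5,
                               stats::runif(nd, 25, 46),
                               stats::runif(nd, 95, 130))
      s[debris_mask] <- stats::runif(nd, 0.55, 0.95)
      v[debris_mask] <- stats::runif(nd, 0.40, 0.80)
      chromatic <- chromatic | debris_mask
    }

    # canopy pixels: exact planted counts of brown / yellow, rest green
    idx <- sample(which(canopy))
    brown_px <- idx[seq_len(n_b)]
    yellow_px <- idx[n_b + seq_len(n_y)]
    green_px <- if (n_b + n_y > 0L) idx[-seq_len(n_b + n_y)] else idx
    h[brown_px] <- stats::runif(n_b, 25, 46)
    h[yellow_px] <- stats::runif(n_y, 55, 76)
    h[green_px] <- stats::runif(length(green_px), 95, 130)
    # saturation * value >= 0.525 keeps the 8-bit hue quantization error
    # under ~0.23 degrees per store/convert cycle, so planted hues survive
    # the generate -> calibrate -> re-store chain with < 1 degree drift
    s[canopy] <- stats::runif(n_c, 0.75, 0.95)
    v[canopy] <- stats::runif(n_c, 0.70, 0.90)
    chromatic <- chromatic | canopy

    layout <- NULL
    if (with_chart) {
      layout <- chart_layout()
      gp <- layout$patches$grey
      h[gp$rows, gp$cols] <- 0
      s[gp$rows, gp$cols] <- 0
      v[gp$rows, gp$cols] <- layout$grey_level +
        stats::runif(length(gp$rows) * length(gp$cols), -0.03, 0.03)
      for (nm in c("green", "brown", "yellow")) {
        p <- layout$patches[[nm]]
        np <- length(p$rows) * length(p$cols)
        # small per-pixel jitter dithers the 8-bit hue quantization so the
        # circular mean estimates the planted patch hue to < 0.1 degree
        h[p$rows, p$cols] <- layout$ref_hues[[nm]] + chart_drift +
          stats::runif(np, -0.75, 0.75)
        s[p$rows, p$cols] <- stats::runif(np, 0.80, 0.90)
        v[p$rows, p$cols] <- stats::runif(np, 0.80, 0.90)
        chromatic[p$rows, p$cols] <- TRUE
      }
    }

    if (hue_shift != 0) {
      h[chromatic] <- h[chromatic] + hue_shift
    }
    h <- h %% 360

    image <- quantize8(hsv_to_rgb(
      structure(list(h = h, s = s, v = v), class = "idc_hsv")))
    structure(list(
      image = image,
      truth_mask = canopy,
      planted_yellow_pct = y,
      planted_brown_pct = b,
      rating = bayes_rating(y, b),
      chart_drift = if (with_chart) chart_drift + hue_shift else 0,
      chart_layout = layout,
      metadata = metadata
    ), class = "idc_sample")
  })
}

#' Generate a synthetic field-experiment catalog
#'
#' Emulates a plots x replications x time-points acquisition design.
#' Every plot follows a non-decreasing severity trajectory across time
#' points (symptoms progress, never regress), and features are drawn from
#' the rating-conditional spec. The catalog carries planted features and
#' ratings; images for individual records can be rendered on demand with
#' [generate_canopy_image()].
#'
#' @param n_plots,n_reps,n_timepoints design factors (all >= 1).
#' @param spec an `idc_feature_spec` for the rating-conditional features.
#' @param seed integer RNG seed.
#' @param p_progress per-step probability that a plot's severity advances
#'   one rating between consecutive time points.
#' @return data.frame with one row per record (`n_plots * n_reps *
#'   n_timepoints` rows): `plot`, `rep`, `timepoint`, `yellow_pct`,
#'   `brown_pct`, `rating`.
#' @export
generate_experiment <- function(n_plots, n_reps, n_timepoints,
                                spec = feature_spec(), seed = 1,
                                p_progress = 0.35) {
  if (n_plots < 1 || n_reps < 1 || n_timepoints < 1) {
    idc_error("idc_invalid_input", "all design counts must be >= 1")
  }
  with_seed(seed, {
    # per-plot monotone severity trajectory
    traj <- matrix(0L, n_plots, n_timepoints)
    traj[, 1] <- sample.int(5L, n_plots, replace = TRUE, prob = spec$priors)
    if (n_timepoints > 1) {
      for (t in 2:n_timepoints) {
        adv <- stats::rbinom(n_plots, 1L, p_progress)
        traj[, t] <- pmin(5L, traj[, t - 1] + adv)
      }
    }
    grid <- expand.grid(plot = seq_len(n_plots), rep = seq_len(n_reps),
                        timepoint = seq_len(n_timepoints))
    grid <- grid[order(grid$plot, grid$rep, grid$timepoint), ]
    rownames(grid) <- NULL
    rating <- traj[cbind(grid$plot, grid$timepoint)]
    feat <- matrix(NA_real_, nrow(grid), 2)
    for (r in 1:5) {
      i <- which(rating == r)
      if (length(i) > 0L) {
        feat[i, ] <- draw_class_features(length(i), spec$means[r, ],
                                         spec$sds[r, ])
      }
    }
    data.frame(grid, yellow_pct = feat[, 1], brown_pct = feat[, 2],
               rating = as.integer(rating))
  })
}

#' @export
print.idc_sample <- function(x, ...) {
  cat(sprintf(
    "synthetic canopy %dx%d: planted Y%% = %.1f, B%% = %.1f, rating %d, %d canopy px%s\n",
    nrow(x$truth_mask), ncol(x$truth_mask), x$planted_yellow_pct,
    x$planted_brown_pct, x$rating, sum(x$truth_mask),
    if (!is.null(x$chart_layout)) sprintf(", chart drift %+.1f deg", x$chart_drift)
    else ""))
  invisible(x)
}
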