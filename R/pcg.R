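#' Population canopy graph
#'
#' Queries a trained classifier at every point of a uniform (Y%, B%) grid
#' and records the predicted rating, producing the decision-boundary map
#' of severity over the feature plane. By default the grid covers the
#' feasible simplex Y + B <= 100 (both features are area fractions of the
#' same canopy); `domain = "square"` queries the full square instead.
#'
#' @param model a fitted `idc_model`.
#' @param step grid step in percent, in (0, 10].
#' @param domain `"simplex"` (default) or `"square"`.
#' @return an object of class `idc_pcg`: list with `grid` (data.frame
#'   `yellow_pct`, `brown_pct`, `rating`), `step`, `domain` and
#'   `model_kind`.
#' @export
population_canopy_graph <- function(model, step = 0.5,
                                    domain = c("simplex", "square")) {
  stopifnot(inherits(model, "idc_model"))
  domain <- match.arg(domain)
  if (!is.numeric(step) || step <= 0 || step > 10) {
    idc_error("idc_invalid_input", "step must be in (0, 10] percent")
  }
  ax <- seq(0, 100, by = step)
  g <- expand.grid(yellow_pct = ax, brown_pct = ax)
  if (domain == "simplex") {
    g <- g[g$yellow_pct + g$brown_pct <= 100 + 1e-9, , drop = FALSE]
  }
  rownames(g) <- NULL
  g$rating <- predict(model, g)
  structure(list(grid = g, step = step, domain = domain,
                 model_kind = model$kind),
            class = "idc_pcg")
}

#' @export
print.idc_pcg <- function(x, ...) {
  cat(sprintf(
    "population canopy graph: %s model, %s domain, step %.2f%%, %d grid points, ratings {%s}\n",
    x$model_kind, x$domain, x$step, nrow(x$grid),
    paste(sort(unique(x$grid$rating)), collapse = ",")))
  invisible(x)
}

# Index the grid as a matrix (rows = B levels, cols = Y levels);
# cells outside the simplex carry NA.
pcg_matrix <- function(pcg) {
  ax <- seq(0, 100, by = pcg$step)
  m <- matrix(NA_integer_, length(ax), length(ax),
              dimnames = list(B = ax, Y = ax))
  i <- match(round(pcg$grid$brown_pct / pcg$step), round(ax / pcg$step))
  j <- match(round(pcg$grid$yellow_pct / pcg$step), round(ax / pcg$step))
  m[cbind(i, j)] <- pcg$grid$rating
  m
}

#' Extract decision boundaries from a population canopy graph
#'
#' Emits one short segment for every pair of adjacent grid cells (in the
#' Y or B direction) whose predicted ratings differ; each segment is the
#' perpendicular bisector of the cell pair and is labeled with the two
#' ratings it separates.
#'
#' @param pcg an `idc_pcg`.
#' @return data.frame with columns `y0`, `b0`, `y1`, `b1` (segment
#'   endpoints in feature coordinates) and `rating_a`, `rating_b`
#'   (`rating_a < rating_b`). Zero rows for a constant grid.
#' @export
extract_boundaries <- function(pcg) {
  stopifnot(inherits(pcg, "idc_pcg"))
  m <- pcg_matrix(pcg)
  s <- pcg$step
  ax <- as.numeric(rownames(m))
  segs <- list()
  add <- function(y0, b0, y1, b1, ra, rb) {
    segs[[length(segs) + 1L]] <<- data.frame(
      y0 = y0, b0 = b0, y1 = y1, b1 = b1,
      rating_a = pmin(ra, rb), rating_b = pmax(ra, rb))
  }
  nr <- nrow(m)
  # neighbors along B (rows)
  a <- m[-nr, , drop = FALSE]; b <- m[-1, , drop = FALSE]
  d <- which(!is.na(a) & !is.na(b) & a != b, arr.ind = TRUE)
  if (nrow(d) > 0) {
    bmid <- ax[d[, 1]] + s / 2
    yc <- ax[d[, 2]]
    add(yc - s / 2, bmid, yc + s / 2, bmid, a[d], b[d])
  }
  # neighbors along Y (cols)
  a <- m[, -ncol(m), drop = FALSE]; b <- m[, -1, drop = FALSE]
  d <- which(!is.na(a) & !is.na(b) & a != b, arr.ind = TRUE)
  if (nrow(d) > 0) {
    ymid <- ax[d[, 2]] + s / 2
    bc <- ax[d[, 1]]
    add(ymid, bc - s / 2, ymid, bc + s / 2, a[d], b[d])
  }
  if (length(segs) == 0L) {
    return(data.frame(y0 = numeric(0), b0 = numeric(0), y1 = numeric(0),
                      b1 = numeric(0), rating_a = integer(0),
                      rating_b = integer(0)))
  }
  do.call(rbind, segs)
}

#' Objective interpretability checks on a population canopy graph
#'
#' Replaces a subjective low/medium/high interpretability judgment with
#' three descriptive checks grounded in how experts rate IDC:
#' (a) ratings 1--3 should occur only at low brown values (minimal
#' necrosis) -- reported as the fraction of rating-1..3 grid area with
#' B <= `b_low_threshold`; (b) beyond some necrosis level every plant is
#' rated 5 -- reported as the lowest grid B level above which all
#' predictions are 5 (vacuously true for a constant grid); (c) each
#' rating's region should be contiguous (one connected component), since
#' severity varies smoothly over the feature plane.
#'
#' @param pcg an `idc_pcg`.
#' @param b_low_threshold "low brown" cutoff in percent for check (a).
#' @param annotation optional free-text expert annotation carried in the
#'   report.
#' @return list of class `idc_interpretability` with elements
#'   `low_ratings_low_brown` (fraction, `NA` when no rating 1--3 points),
#'   `rating5_b_level` (numeric or `NA`), `rating5_vacuous`,
#'   `components_per_rating` (named integer), per-check `pass` flags and
#'   `all_pass`.
#' @export
interpretability_checklist <- function(pcg, b_low_threshold = 15,
                                       annotation = "") {
  stopifnot(inherits(pcg, "idc_pcg"))
  g <- pcg$grid
  low <- g[g$rating <= 3L, , drop = FALSE]
  frac_low_b <- if (nrow(low) == 0L) NA_real_ else
    mean(low$brown_pct <= b_low_threshold)
  pass_a <- !is.na(frac_low_b) && frac_low_b >= 0.95

  m <- pcg_matrix(pcg)
  blevels <- as.numeric(rownames(m))
  all5 <- vapply(seq_along(blevels), function(i) {
    r <- m[i, ]
    all(is.na(r)) || all(r[!is.na(r)] == 5L)
  }, logical(1))
  # longest all-5 suffix of B levels
  not5 <- which(!all5)
  if (length(not5) == 0L) {
    first5 <- 1L
  } else if (max(not5) == length(blevels)) {
    first5 <- NA_integer_
  } else {
    first5 <- max(not5) + 1L
  }
  constant <- length(unique(g$rating)) == 1L
  if (!is.na(first5)) {
    b_level <- blevels[first5]
    vacuous <- all(is.na(m[first5:length(blevels), ]))
    pass_b <- TRUE
  } else if (constant) {
    b_level <- NA_real_; vacuous <- TRUE; pass_b <- TRUE
  } else {
    b_level <- NA_real_; vacuous <- FALSE; pass_b <- FALSE
  }

  ratings <- sort(unique(g$rating))
  comps <- vapply(ratings, function(r) {
    mask <- !is.na(m) & m == r
    length(connected_components(mask, 4)$sizes)
  }, integer(1))
  names(comps) <- ratings
  pass_c <- all(comps == 1L)

  structure(list(
    low_ratings_low_brown = frac_low_b,
    b_low_threshold = b_low_threshold,
    pass_low_brown = pass_a,
    rating5_b_level = b_level,
    rating5_vacuous = vacuous,
    pass_rating5 = pass_b,
    components_per_rating = comps,
    pass_contiguity = pass_c,
    all_pass = pass_a && pass_b && pass_c,
    annotation = annotation
  ), class = "idc_interpretability")
}

#' @export
print.idc_interpretability <- function(x, ...) {
  cat("PCG interpretability checklist\n")
  cat(sprintf(" (a) ratings 1-3 at B <= %.0f%%: %s  [%s]\n",
              x$b_low_threshold,
              if (is.na(x$low_ratings_low_brown)) "degenerate (no rating 1-3 points)"
              else sprintf("%.1f%% of area", 100 * x$low_ratings_low_brown),
              if (x$pass_low_brown) "pass" else "FAIL"))
  cat(sprintf(" (b) all-rating-5 above B = %s%s  [%s]\n",
              if (is.na(x$rating5_b_level)) "-" else
                sprintf("%.1f%%", x$rating5_b_level),
              if (x$rating5_vacuous) " (vacuous)" else "",
              if (x$pass_rating5) "pass" else "FAIL"))
  cat(sprintf(" (c) connected components per rating: %s  [%s]\n",
              paste(sprintf("%s:%d", names(x$components_per_rating),
                            x$components_per_rating), collapse = " "),
              if (x$pass_contiguity) "pass" else "FAIL"))
  if (nzchar(x$annotation)) cat(" note:", x$annotation, "\n")
  invisible(x)
}

#' Plot a population canopy graph
#'
#' Colored map of predicted ratings over the (Y%, B%) plane with the
#' extracted decision boundaries overlaid.
#'
#' @param x an `idc_pcg`.
#' @param boundaries draw boundary segments?
#' @param ... passed to [graphics::image()].
#' @export
plot.idc_pcg <- function(x, boundaries = TRUE, ...) {
  m <- pcg_matrix(x)
  ax <- as.numeric(rownames(m))
  pal <- c("#1a9850", "#a6d96a", "#fee08b", "#f46d43", "#a50026")
  graphics::image(ax, ax, t(m), col = pal, zlim = c(1, 5),
                  xlab = "yellow canopy area (Y%)",
                  ylab = "brown canopy area (B%)",
                  main = sprintf("Population canopy graph (%s)", x$model_kind),
                  useRaster = TRUE, ...)
  if (boundaries) {
    segs <- extract_boundaries(x)
    if (nrow(segs) > 0) {
      graphics::segments(segs$y0, segs$b0, segs$y1, segs$b1, lwd = 0.5)
    }
  }
  graphics::legend("topright", legend = paste("rating", 1:5), fill = pal,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Export a population canopy graph
#'
#' @param pcg an `idc_pcg`.
#' @param csv_path grid CSV (`yellow_pct`, `brown_pct`, `rating`).
#' @param boundaries_json_path optional JSON line list of boundary
#'   segments.
#' @return invisibly, `pcg`.
#' @export
write_pcg <- function(pcg, csv_path, boundaries_json_path = NULL) {
  utils::write.csv(pcg$grid, csv_path, row.names = FALSE)
  if (!is.null(boundaries_json_path)) {
    segs <- extract_boundaries(pcg)
    lines <- lapply(seq_len(nrow(segs)), function(i) {
      list(type = "LineString",
           coordinates = list(c(segs$y0[i], segs$b0[i]),
                              c(segs$y1[i], segs$b1[i])),
           ratings = c(segs$rating_a[i], segs$rating_b[i]))
    })
    jsonlite::write_json(lines, boundaries_json_path, auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(pcg)
}
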