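test_that("planted fractions are realized exactly by the generator", {
  # zero discoloration: every canopy pixel in the green band
  s <- generate_canopy_image(0, 0, seed = 1)
  hsv <- to_hsv(s$image)
  h <- floor(hsv$h[s$truth_mask] + 0.5)
  expect_true(all(h >= 81 & h <= 140))

  # planted (20, 5) recovered by feature extraction over the truth mask
  s <- generate_canopy_image(20, 5, size = 512, seed = 7)
  hsv <- to_hsv(s$image)
  mask <- structure(list(mask = s$truth_mask,
                         canopy_pixel_count = sum(s$truth_mask)),
                    class = "idc_mask")
  f <- extract_features(classify_canopy_pixels(hsv, mask))
  eps <- 100 / sum(s$truth_mask)
  expect_lt(abs(f$yellow_pct - 20), eps)
  expect_lt(abs(f$brown_pct - 5), eps)
})

test_that("generator rejects invalid inputs", {
  expect_error(generate_canopy_image(60, 50), class = "idc_invalid_input")
  expect_error(generate_canopy_image(-1, 0), class = "idc_invalid_input")
  expect_error(generate_canopy_image(10, 5, size = 64),
               class = "idc_invalid_input")
})

test_that("truth mask is one connected component larger than any debris", {
  for (seed in 1:3) {
    s <- generate_canopy_image(30, 10, n_debris = 4, seed = seed)
    cc <- connected_components(s$truth_mask, 8)
    expect_length(cc$sizes, 1)
    # debris blobs in the thresholded image are all smaller than the canopy
    fg <- threshold_foreground(to_hsv(s$image), seg_config())
    all_cc <- connected_components(fg, 8)
    expect_equal(max(all_cc$sizes), sum(s$truth_mask))
    expect_true(all(all_cc$sizes[-which.max(all_cc$sizes)] <
                      sum(s$truth_mask)))
  }
})

test_that("feature tables are reproducible and respect the simplex", {
  t1 <- generate_feature_table(n = 1000, seed = 0)
  t2 <- generate_feature_table(n = 1000, seed = 0)
  expect_identical(t1, t2)
  expect_true(all(t1$yellow_pct >= 0 & t1$brown_pct >= 0))
  expect_true(all(t1$yellow_pct + t1$brown_pct <= 100))
  expect_true(all(t1$rating %in% 1:5))

  # degenerate prior: all mass on rating 3
  spec3 <- feature_spec(priors = c(0, 0, 1, 0, 0))
  t3 <- generate_feature_table(spec3, n = 50, seed = 1)
  expect_true(all(t3$rating == 3L))

  expect_error(feature_spec(sds = matrix(-1, 5, 2)),
               class = "idc_invalid_input")
})

test_that("per-class sample means converge to the spec locations", {
  spec <- feature_spec()
  tab <- generate_feature_table(spec, n = 10000, seed = 123)
  for (r in 1:5) {
    rows <- tab[tab$rating == r, ]
    for (j in 1:2) {
      x <- rows[[j]]
      se <- spec$sds[r, j] / sqrt(nrow(rows))
      expect_lt(abs(mean(x) - spec$means[r, j]), 3 * se)
    }
  }
})

test_that("experiment catalogs have the full factorial cardinality", {
  cat1 <- generate_experiment(7, 4, 3, seed = 0)
  expect_equal(nrow(cat1), 7 * 4 * 3)
  expect_equal(nrow(cat1[cat1$timepoint == 1, ]), 28)
  expect_equal(nrow(generate_experiment(1, 1, 1, seed = 0)), 1)
  expect_error(generate_experiment(0, 4, 3), class = "idc_invalid_input")
})

test_that("severity never regresses across time points within a plot", {
  cat1 <- generate_experiment(50, 2, 3, seed = 5)
  for (p in unique(cat1$plot)) {
    sub <- cat1[cat1$plot == p, ]
    by_tp <- tapply(sub$rating, sub$timepoint, unique)
    expect_true(all(lengths(by_tp) == 1))   # one severity per plot/timepoint
    expect_true(all(diff(as.integer(by_tp)) >= 0))
  }
})

test_that("ground-truth rating rule is monotone with a hard necrosis cap", {
  expect_identical(bayes_rating(0, 0), 1L)
  # above the necrosis threshold every canopy is rated 5, whatever Y
  for (y in c(0, 10, 40, 80)) {
    expect_identical(bayes_rating(y, 16), 5L)
  }
  expect_error(bayes_rating(60, 50), class = "idc_invalid_input")

  # exhaustive 1%-grid sweep: non-decreasing in B at fixed Y (and in Y)
  for (y in seq(0, 100, 1)) {
    b <- seq(0, 100 - y, 1)
    r <- bayes_rating(rep(y, length(b)), b)
    expect_true(all(diff(r) >= 0))
  }
  g <- probe_grid(1)
  r <- bayes_rating(g$yellow_pct, g$brown_pct)
  # ratings 1-3 occur only at low brown
  expect_true(all(g$brown_pct[r <= 3] <= 15))
})
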