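make_pcg <- function(grid, step) {
  structure(list(grid = grid, step = step, domain = "simplex",
                 model_kind = "test"), class = "idc_pcg")
}

constant_pcg <- function(rating, step = 5) {
  g <- probe_grid(step)
  g$rating <- as.integer(rating)
  make_pcg(g, step)
}

test_that("the grid covers the simplex with the triangular count", {
  m <- bayes_model()
  for (step in c(0.5, 1, 2)) {
    pcg <- population_canopy_graph(m, step = step)
    k <- 100 / step
    expect_equal(nrow(pcg$grid), (k + 1) * (k + 2) / 2)
    expect_true(all(pcg$grid$yellow_pct + pcg$grid$brown_pct <= 100 + 1e-9))
  }
  expect_error(population_canopy_graph(m, step = 0),
               class = "idc_invalid_input")
})

test_that("grid predictions agree with direct classifier calls", {
  tab <- separable_table()
  m <- idc_train(tab, "hier_svm_svm", seed = 1)
  pcg <- population_canopy_graph(m, step = 2)
  set.seed(3)
  idx <- sample(nrow(pcg$grid), 50)
  expect_identical(pcg$grid$rating[idx],
                   predict(m, pcg$grid[idx, c("yellow_pct", "brown_pct")]))
})

test_that("refining the step preserves ratings at coincident points", {
  m <- bayes_model()
  coarse <- population_canopy_graph(m, step = 1)
  fine <- population_canopy_graph(m, step = 0.5)
  key <- function(g) paste(g$yellow_pct, g$brown_pct)
  common <- match(key(coarse$grid), key(fine$grid))
  expect_false(anyNA(common))
  expect_identical(coarse$grid$rating, fine$grid$rating[common])
})

test_that("boundary extraction finds edges between differing neighbors", {
  expect_equal(nrow(extract_boundaries(constant_pcg(1))), 0)

  # vertical half-plane split at Y = 50: one straight boundary
  g <- probe_grid(5)
  g$rating <- ifelse(g$yellow_pct < 50, 1L, 2L)
  segs <- extract_boundaries(make_pcg(g, 5))
  expect_true(all(segs$rating_a == 1 & segs$rating_b == 2))
  # all segments lie on the line Y = 47.5 (between 45 and 50)
  expect_true(all(segs$y0 == 47.5 & segs$y1 == 47.5))

  # boundaries partition the grid into contiguous same-rating regions
  pcgb <- population_canopy_graph(bayes_model(), step = 1)
  chk <- interpretability_checklist(pcgb)
  expect_true(chk$pass_contiguity)
})

test_that("the ground-truth rule passes every interpretability check", {
  pcg <- population_canopy_graph(bayes_model(), step = 1)
  chk <- interpretability_checklist(pcg)
  expect_true(chk$pass_low_brown)
  expect_equal(chk$low_ratings_low_brown, 1)   # all 1-3 area at low B
  expect_true(chk$pass_rating5)
  expect_false(chk$rating5_vacuous)
  expect_lte(chk$rating5_b_level, 16)
  expect_true(chk$pass_contiguity)
  expect_true(chk$all_pass)
})

test_that("degenerate and adversarial grids are reported honestly", {
  # constant rating-1 grid: necrosis check passes vacuously, low-brown
  # fraction is defined, contiguity trivially holds
  chk1 <- interpretability_checklist(constant_pcg(1))
  expect_true(chk1$pass_rating5)
  expect_true(chk1$rating5_vacuous)
  expect_true(chk1$pass_contiguity)

  # constant rating-5 grid: low-brown check degenerates to NA
  chk5 <- interpretability_checklist(constant_pcg(5))
  expect_true(is.na(chk5$low_ratings_low_brown))
  expect_false(chk5$pass_low_brown)

  # randomly labeled grid cannot be contiguous
  g <- probe_grid(2)
  set.seed(8)
  g$rating <- sample(1:5, nrow(g), replace = TRUE)
  chkr <- interpretability_checklist(make_pcg(g, 2))
  expect_false(chkr$pass_contiguity)
})

test_that("the trained rating-5 boundary is nearly horizontal over its support", {
  tab <- generate_feature_table(n = 2000, seed = 11)
  sp <- split_train_test(tab, 0.75, seed = 11)
  m <- idc_train(sp$train, "hier_svm_svm", seed = 11)
  pcg <- population_canopy_graph(m, step = 1)
  g <- pcg$grid
  # measure where the rating-5 class has training support (central 90%)
  y5 <- sp$train$yellow_pct[sp$train$rating == 5]
  qs <- stats::quantile(y5, c(0.05, 0.95))
  sel <- g$rating == 5 & g$yellow_pct >= qs[1] & g$yellow_pct <= qs[2]
  b5 <- tapply(g$brown_pct[sel], g$yellow_pct[sel], min)
  expect_lt(max(b5) - min(b5), 5)
})

test_that("PCG grids and boundaries export cleanly", {
  pcg <- population_canopy_graph(bayes_model(), step = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  bjson <- withr::local_tempfile(fileext = ".json")
  write_pcg(pcg, csv, bjson)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(pcg$grid))
  segs <- jsonlite::read_json(bjson, simplifyVector = TRUE)
  expect_gt(length(segs$type), 0)
  expect_equal(segs$type[[1]], "LineString")
})
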