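test_that("RGB to HSV follows the hue-circle conventions", {
  img <- array(0, dim = c(1, 3, 3))
  img[1, 1, ] <- c(1, 0, 0)      # pure red
  img[1, 2, ] <- c(0.5, 0.5, 0.5) # grey
  img[1, 3, ] <- c(0, 1, 0)      # pure green
  hsv <- to_hsv(img)
  expect_equal(hsv$h[1, 1], 0)
  expect_equal(hsv$s[1, 2], 0)
  expect_equal(hsv$h[1, 3], 120)
})

test_that("HSV conversion round-trips within one intensity level", {
  # sampled 8-bit color cube
  lv <- seq(0, 255, by = 17) / 255
  cube <- expand.grid(r = lv, g = lv, b = lv)
  img <- array(c(cube$r, cube$g, cube$b), dim = c(nrow(cube), 1, 3))
  back <- idcscore:::hsv_to_rgb(to_hsv(img))
  expect_lt(max(abs(back - img)), 1.5 / 255)
})

test_that("foreground thresholding keeps saturated in-window hues only", {
  mk <- function(h, s, v = 0.5) {
    idcscore:::hsv_to_rgb(structure(
      list(h = matrix(h), s = matrix(s), v = matrix(v)), class = "idc_hsv"))
  }
  cfg <- seg_config()
  expect_false(any(threshold_foreground(to_hsv(mk(100, 0)), cfg)))  # grey
  expect_true(all(threshold_foreground(to_hsv(mk(35, 0.8)), cfg)))  # brown
  expect_false(any(threshold_foreground(to_hsv(mk(300, 0.8)), cfg))) # magenta
  expect_false(any(threshold_foreground(to_hsv(mk(35, 0.05)), cfg))) # dull soil
})

test_that("raising the saturation floor never adds foreground pixels", {
  s <- generate_canopy_image(30, 10, seed = 6)
  hsv <- to_hsv(s$image)
  prev <- threshold_foreground(hsv, seg_config(sat_min = 0))
  for (sm in c(0.1, 0.15, 0.3, 0.6, 0.9)) {
    cur <- threshold_foreground(hsv, seg_config(sat_min = sm))
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("connected components handle simple constructed cases", {
  empty <- matrix(FALSE, 8, 8)
  expect_length(connected_components(empty, 8)$sizes, 0)

  two <- matrix(FALSE, 10, 10)
  two[2:4, 2:4] <- TRUE
  two[7:9, 7:9] <- TRUE
  cc4 <- connected_components(two, 4)
  expect_equal(sort(cc4$sizes), c(9, 9))
  expect_length(cc4$sizes, 2)
  # diagonal touch merges under 8- but not 4-connectivity
  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_length(connected_components(diag2, 4)$sizes, 2)
  expect_length(connected_components(diag2, 8)$sizes, 1)
})

test_that("labeling matches a flood-fill oracle on random masks", {
  set.seed(7)
  for (i in 1:100) {
    mask <- matrix(runif(256) < 0.4, 16, 16)
    conn <- if (i %% 2 == 0) 4 else 8
    got <- connected_components(mask, conn)
    want <- flood_fill_label(mask, conn)
    expect_true(same_partition(got$labels, want))
    expect_equal(sum(got$sizes), sum(mask))
    expect_equal(sort(got$sizes),
                 sort(as.integer(table(want[want > 0]))))
  }
})

test_that("largest_component keeps the biggest blob, center on ties", {
  m <- matrix(FALSE, 30, 30)
  m[5:14, 5:14] <- TRUE    # 100 px
  m[20:22, 20:22] <- TRUE  # 9 px
  m[28, 28] <- TRUE
  keep <- largest_component(m, 8)
  expect_equal(keep$canopy_pixel_count, 100)
  expect_true(all(which(keep$mask) == which(m & row(m) <= 14)))

  single <- matrix(FALSE, 10, 10); single[3:5, 3:5] <- TRUE
  expect_equal(largest_component(single, 8)$mask, single)

  # equal sizes: component nearest the image center wins
  tie <- matrix(FALSE, 21, 21)
  tie[9:13, 9:13] <- TRUE          # centered, 25 px
  tie[1:5, 17:21] <- TRUE          # corner, 25 px
  keep <- largest_component(tie, 8)
  expect_true(keep$mask[11, 11])
  expect_false(keep$mask[2, 19])

  expect_error(largest_component(matrix(FALSE, 5, 5), 8),
               class = "idc_no_canopy")
})

test_that("segment_canopy recovers the generated truth mask", {
  for (seed in c(1, 8)) {
    s <- generate_canopy_image(25, 10, n_debris = 4, seed = seed)
    m <- segment_canopy(s$image)
    jacc <- sum(m$mask & s$truth_mask) / sum(m$mask | s$truth_mask)
    expect_gte(jacc, 0.99)
    expect_length(connected_components(m$mask, 8)$sizes, 1)
  }
  expect_error(segment_canopy(soil_image()), class = "idc_no_canopy")
  # identity profile leaves the mask unchanged on a drift-free image
  s <- generate_canopy_image(25, 10, seed = 1)
  m0 <- segment_canopy(s$image)
  m1 <- segment_canopy(s$image, profile = calibration_profile())
  expect_identical(m0$mask, m1$mask)
})
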