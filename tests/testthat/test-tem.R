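test_that("transects of a uniform field are constant and span width plus margin", {
  g <- rod_geometry(c(2, 2), 0, 3, 1)
  img <- matrix(11, 134, 134)
  tr <- midcell_transect(img, g, pixel_size_nm = 30, margin_nm = 90)
  expect_true(all(abs(tr$intensity - 11) < 1e-9))
  expect_equal(max(tr$position_nm), 570, tolerance = 30)
  expect_equal(tr$position_nm, -rev(tr$position_nm))
  expect_true(all(diff(tr$position_nm) > 0))
  expect_error(midcell_transect(img, g, 30, margin_nm = 5000), "exits")
})

test_that("constructed Gaussian dips are localised to subpixel accuracy", {
  x <- 0:90
  y <- 100 - 60 * exp(-(x - 30)^2 / 8) - 60 * exp(-(x - 60)^2 / 8)
  tr <- hand_transect(y, pixel_size_nm = 5)
  pk <- detect_layer_peaks(tr, smooth_px = 0)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$position_nm, c(150, 300), tolerance = 2.5)
  # constant transect: nothing to find
  expect_identical(nrow(detect_layer_peaks(hand_transect(rep(3, 50)))), 0L)
  # a dip below the prominence threshold is excluded
  y2 <- 100 - 60 * exp(-(x - 30)^2 / 8) - 5 * exp(-(x - 60)^2 / 8)
  pk2 <- detect_layer_peaks(hand_transect(y2, 5), prominence_frac = 0.2,
                            smooth_px = 0)
  expect_identical(nrow(pk2), 1L)
  expect_equal(pk2$position_nm, 150, tolerance = 2.5)
})

test_that("peak positions are translation-equivariant", {
  x <- 0:120
  base <- function(sh) 80 - 50 * exp(-(x - 40 - sh)^2 / 10) -
    50 * exp(-(x - 80 - sh)^2 / 10)
  p0 <- detect_layer_peaks(hand_transect(base(0), 5), smooth_px = 0)
  p7 <- detect_layer_peaks(hand_transect(base(7), 5), smooth_px = 0)
  expect_equal(p7$position_nm, p0$position_nm + 35, tolerance = 0.1)
})

test_that("subpixel refinement beats integer-sample positions", {
  set.seed(9)
  err_ref <- err_int <- numeric(100)
  x <- 0:60
  for (i in 1:100) {
    c0 <- runif(1, 25, 35)
    y <- 100 - 70 * exp(-(x - c0)^2 / 12) + rnorm(61, 0, 0.5)
    tr <- hand_transect(y, 5)
    pr <- detect_layer_peaks(tr, smooth_px = 1, refine = TRUE)
    pi_ <- detect_layer_peaks(tr, smooth_px = 1, refine = FALSE)
    err_ref[i] <- min(abs(pr$position_nm - c0 * 5))
    err_int[i] <- min(abs(pi_$position_nm - c0 * 5))
  }
  expect_lt(mean(err_ref), mean(err_int))
})

test_that("layer counting excludes the plasma membrane and splits by side", {
  g <- rod_geometry(c(0, 0), 0, 3, 1)
  empty <- detect_layer_peaks(hand_transect(rep(1, 30)))
  lc0 <- suppressWarnings(layer_counts(empty, g))
  expect_identical(c(lc0$side1, lc0$side2), c(0L, 0L))

  # GL-like scene: 3 thylakoid layers per side
  s <- make_scene(scene_params(preset = "GL",
                               distribution = protein_distribution(0),
                               optics = tem_optics()), seed = 41)
  r <- render_tem(s, noise = FALSE)
  tr <- midcell_transect(r$image, s$geometry, 5)
  lc <- layer_counts(detect_layer_peaks(tr), s$geometry)
  expect_identical(c(lc$side1, lc$side2), c(3L, 3L))
  expect_true(all(lc$pm_found))

  # HL-like scene: fragment + continuous layer on side 1, layer only on side 2
  sh <- make_scene(scene_params(preset = "HL",
                                distribution = protein_distribution(0),
                                optics = tem_optics()), seed = 42)
  rh <- render_tem(sh, noise = FALSE)
  trh <- midcell_transect(rh$image, sh$geometry, 5)
  lch <- layer_counts(detect_layer_peaks(trh), sh$geometry)
  expect_identical(c(lch$side1, lch$side2), c(2L, 1L))
})

test_that("spacing summaries report mean, SD, n, percent change and the t test", {
  ss <- spacing_summary(list(A = c(100, 110, 120), B = c(100, 110, 120)), "A")
  tb <- ss$table
  expect_equal(tb$percent_change[tb$group == "B"], 0)
  expect_equal(tb$mean_nm[1], 110)
  expect_equal(tb$sd_nm[1], 10)
  expect_identical(tb$n[1], 3L)
  expect_error(spacing_summary(list(A = 1:3), "Z"), "unknown reference")
  expect_error(spacing_summary(list(A = numeric(), B = 1:3), "B"), "non-empty")
})

test_that("group means 78.4 and 109.2 nm give a ~39% spacing increase", {
  gl <- 78.4 + c(-2, -1, 0, 1, 2)
  hl <- 109.2 + c(-2, -1, 0, 1, 2)
  ss <- spacing_summary(list(GL = gl, HL = hl), "GL")
  pc <- ss$table$percent_change[ss$table$group == "HL"]
  expect_equal(round(pc), 39)
  expect_equal(pc, 100 * (109.2 - 78.4) / 78.4, tolerance = 1e-12)
})
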