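fixture_contour <- function(orientation = 0, L = 3, W = 1, px = 30,
                            dim = c(160, 160)) {
  g <- rod_geometry(c(dim[1] * px / 2000, dim[2] * px / 2000), orientation, L, W)
  m <- footprint_mask(g, dim, px)
  list(g = g, m = m, ct = extract_anchored_contour(m, g, px))
}

test_that("a constant field samples to a constant profile of exactly n points", {
  fx <- fixture_contour()
  img <- matrix(7.5, 160, 160)
  pr <- sample_periphery(img, fx$ct, band = 1, n = 360)
  expect_length(pr$value, 360)
  expect_equal(pr$position, (0:359) / 360)
  expect_true(all(abs(pr$value - 7.5) < 1e-9))
})

test_that("profile argmax recovers a ground-truth bright point at arc 0.25", {
  s <- hand_scene(proteins = data.frame(t = 0.25, shell = 0L, amplitude = 100,
                                        region = "P1"))
  r <- render_fluorescence(s, noise = FALSE)
  m <- footprint_mask(s$geometry, s$dim, s$optics$pixel_size_nm)
  ct <- extract_anchored_contour(m, s$geometry, s$optics$pixel_size_nm)
  pr <- sample_periphery(r$gfp, ct, band = 1, n = 360)
  expect_lt(abs(pr$position[which.max(pr$value)] - 0.25), 1.5 / 360)
})

test_that("profiles scale linearly with image intensity", {
  fx <- fixture_contour(orientation = 20)
  set.seed(4)
  img <- matrix(runif(160 * 160, 1, 5), 160, 160)
  p1 <- sample_periphery(img, fx$ct)
  p3 <- sample_periphery(3 * img, fx$ct)
  expect_equal(p3$value, 3 * p1$value, tolerance = 1e-12)
})

test_that("profiles are invariant under rigid rotation of image plus contour", {
  pts <- data.frame(t = c(0.12, 0.4, 0.77), shell = 0L,
                    amplitude = c(50, 80, 30), region = "x")
  opt <- optics_params(poisson_gain = 0, read_sigma = 0, background = 0,
                       margin_nm = 700)
  s0 <- hand_scene(proteins = pts, orientation_deg = 0, optics = opt)
  s35 <- hand_scene(proteins = pts, orientation_deg = 35, optics = opt)
  r0 <- render_fluorescence(s0, noise = FALSE)
  r35 <- render_fluorescence(s35, noise = FALSE)
  m0 <- footprint_mask(s0$geometry, s0$dim, 30)
  ct0 <- extract_anchored_contour(m0, s0$geometry, 30)
  # rigidly transform the same contour into the rotated frame
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  c0 <- s0$geometry$center * 1000 / 30
  c35 <- s35$geometry$center * 1000 / 30
  ct35 <- ct0
  ct35$xy_px <- sweep(sweep(ct0$xy_px, 2, c0) %*% t(R), 2, c35, `+`)
  p0 <- sample_periphery(r0$gfp, ct0)
  p35 <- sample_periphery(r35$gfp, ct35)
  expect_lt(max(abs(p0$value - p35$value)) / diff(range(p0$value)), 0.01)
})

test_that("region partition covers all four labels at the analytic fractions", {
  fx <- fixture_contour()
  pr <- sample_periphery(matrix(1, 160, 160), fx$ct)
  pr <- partition_regions(pr, fx$g)
  tab <- table(pr$region)
  expect_setequal(names(tab), c("L1", "L2", "P1", "P2"))
  expect_equal(sum(tab), 360L)
  expect_equal(unname(tab[["P1"]]) / 360, 0.2199, tolerance = 0.01)
  expect_equal(unname(tab[["P2"]]) / 360, 0.2199, tolerance = 0.01)
  expect_equal(unname(tab[["L1"]]) / 360, 0.2800, tolerance = 0.01)
  # sphere limit: sides vanish, operation flags the degeneracy
  gs <- rod_geometry(c(1, 1), 0, 1, 1)
  expect_warning(prs <- partition_regions(pr, gs), "degenerate")
  expect_lt(mean(prs$region %in% c("L1", "L2")), 0.01)
})

test_that("average_profiles is the pointwise arithmetic mean", {
  p1 <- hand_profile(c(1, 2, 3, 4, 5, 6, 7, 8))
  p2 <- hand_profile(c(3, 2, 5, 4, 7, 6, 9, 8))
  mp <- average_profiles(list(p1, p2))
  expect_equal(mp$mean, (p1$value + p2$value) / 2)
  expect_identical(mp$n_cells, 2L)
  same <- average_profiles(rep(list(p1), 5))
  expect_equal(same$mean, p1$value)
  expect_error(average_profiles(list(p1, hand_profile(1:9))), "sample count")
  expect_error(average_profiles(list(p1, hand_profile(1:8, channel = "chl"))),
               "channel")
})

test_that("mean profile over asymmetric cells recovers the side-density ratio", {
  params <- scene_params(distribution = protein_distribution(side_asymmetry = 2,
                                                             kappa = 0))
  st <- simulate_periphery_study(params, n_cells = 12, seed = 301)
  mp <- st$mean_profile
  pr <- hand_profile(mp$mean)
  pr <- partition_regions(pr, rod_geometry(c(0, 0), 0, 3, 1))
  bg <- 10  # generator background pedestal
  lv1 <- stats::median(pr$value[pr$region == "L1"]) - bg
  lv2 <- stats::median(pr$value[pr$region == "L2"]) - bg
  expect_lt(abs(lv1 / lv2 - 2) / 2, 0.15)
})
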