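sd_pop_oracle <- function(x) sqrt(mean((x - mean(x))^2))

test_that("patchiness matches hand arithmetic and its invariances", {
  expect_equal(patchiness(hand_profile(rep(4, 50)))$value, 0)
  # n = 2 profile (1, 3): population SD 1, total 4
  expect_equal(patchiness(hand_profile(c(1, 3)))$value, 0.25)
  # invariant to uniform intensity scaling
  p <- hand_profile(c(2, 9, 4, 7, 1, 5))
  expect_equal(patchiness(hand_profile(17 * p$value))$value, patchiness(p)$value,
               tolerance = 1e-12)
  expect_error(patchiness(hand_profile(rep(0, 10))), "zero total")
  # mean normaliser is the plain coefficient of variation
  expect_equal(patchiness(p, normalizer = "mean")$value,
               sd_pop_oracle(p$value) / mean(p$value))
})

test_that("patchiness equals the definitional brute force on 100 random profiles", {
  set.seed(100)
  for (i in 1:100) {
    v <- runif(sample(20:400, 1), 0, 50)
    expect_equal(patchiness(hand_profile(v))$value, sd_pop_oracle(v) / sum(v),
                 tolerance = 1e-12)
  }
})

test_that("side asymmetry is the brighter/dimmer max ratio, label-free", {
  reg <- rep(c("L1", "P1", "L2", "P2"), each = 5)
  v <- c(2, 10, 3, 2, 2,  1, 1, 1, 1, 1,  5, 4, 5, 2, 1,  1, 1, 1, 1, 1)
  a <- side_asymmetry(hand_profile(v, reg))
  expect_equal(a$value, 2)
  expect_identical(a$brighter_side, "L1")
  # swapping the side labels flips the reported side, not the value
  reg2 <- chartr("12", "21", reg)
  a2 <- side_asymmetry(hand_profile(v, reg2))
  expect_equal(a2$value, 2)
  expect_identical(a2$brighter_side, "L2")
  # mirror-symmetric profile
  vs <- c(1, 2, 3, 2, 1)
  expect_equal(side_asymmetry(hand_profile(rep(vs, 4), reg))$value, 1)
  expect_error(side_asymmetry(hand_profile(v)), "region labels")
  expect_error(side_asymmetry(hand_profile(c(0, 0, 1, 1),
                                           c("L1", "L1", "L2", "L2"))),
               "positive")
})

test_that("Pearson colocalization honours identity, anti-identity and independence", {
  set.seed(5)
  img <- matrix(runif(2500), 50, 50)
  m <- matrix(TRUE, 50, 50)
  expect_equal(pearson_colocalization(img, img, m), 1)
  expect_equal(pearson_colocalization(img, 3 - img, m), -1)
  expect_error(pearson_colocalization(img, matrix(1, 50, 50), m), "variance")
  # two independent noise fields: |r| < 0.05 in at least 99% of 200 runs
  ok <- 0
  for (i in 1:200) {
    set.seed(1000 + i)
    a <- matrix(rnorm(1e4), 100, 100)
    b <- matrix(rnorm(1e4), 100, 100)
    if (abs(pearson_colocalization(a, b, matrix(TRUE, 100, 100))) < 0.05)
      ok <- ok + 1
  }
  expect_gte(ok / 200, 0.99)
})

test_that("pearson_colocalization equals the definitional formula on random inputs", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(50:500, 1)
    a <- rnorm(n); b <- a * runif(1, -2, 2) + rnorm(n)
    A <- matrix(a, n, 1); B <- matrix(b, n, 1)
    r <- pearson_colocalization(A, B, matrix(TRUE, n, 1))
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(r, oracle, tolerance = 1e-12)
  }
})

test_that("Manders coefficients are intensity fractions over the partner's support", {
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- matrix(c(0, 1, 0, 1), 2, 2)
  m <- matrix(TRUE, 2, 2)
  mm <- manders_coefficients(a, b, m)
  expect_equal(unname(mm["M1"]), (2 + 4) / 10)
  expect_equal(unname(mm["M2"]), 1)
})

test_that("compare_groups reproduces the closed-form pooled t", {
  r0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  r <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.288, tolerance = 0.002)
  expect_equal(compare_groups(c(1, 5), c(2, 4, 9))$df, 3)
  expect_error(compare_groups(c(1, 1), c(2, 2)), "undefined")
  expect_equal(compare_groups(c(2, 2), c(2, 2))$p, 1)
})

test_that("compare_groups matches the definitional brute force to 12 digits", {
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(sample(2:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:40, 1), mean = runif(1, -1, 1))
    got <- compare_groups(x, y)
    want <- pooled_t_oracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("compare_groups holds its nominal type-I error", {
  set.seed(8)
  rej <- 0; reps <- 2000
  for (i in 1:reps) {
    if (compare_groups(rnorm(50), rnorm(50))$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.04)
  expect_lte(rej / reps, 0.06)
})
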