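make_table <- function() {
  conds <- condition_levels()
  df <- expand.grid(protein = c("PsaA", "PsbA", "Zero"),
                    condition = conds, replicate = 1:3,
                    stringsAsFactors = FALSE)
  set.seed(11)
  df$abundance <- runif(nrow(df), 1, 10)
  df$abundance[df$protein == "Zero" & df$condition == "GL"] <- 0
  abundance_table(df)
}

test_that("reference normalisation yields unit reference means and drops zero-reference proteins", {
  tb <- make_table()
  expect_message(nt <- normalize_to_reference(tb, "GL"), "Zero")
  expect_identical(attr(nt, "dropped"), "Zero")
  for (p in c("PsaA", "PsbA"))
    expect_equal(mean(nt$abundance[nt$protein == p & nt$condition == "GL"]), 1)
  # value 5 against reference mean 2 -> 2.5
  df <- data.frame(protein = "X", condition = c("GL", "GL", "HL"),
                   replicate = c(1, 2, 1), abundance = c(1, 3, 5))
  n1 <- suppressMessages(normalize_to_reference(abundance_table(df)))
  expect_equal(n1$abundance[n1$condition == "HL"], 2.5)
  # idempotence
  n2 <- suppressMessages(normalize_to_reference(n1))
  expect_equal(n2$abundance, n1$abundance)
  expect_error(normalize_to_reference(abundance_table(
    data.frame(protein = "X", condition = "HL", replicate = 1, abundance = 1)),
    "GL"), "absent")
})

test_that("exact quartic data are interpolated with unit R-squared", {
  x <- 0:6
  co <- c(0.5, -1, 2, 0.3, -0.05)
  y <- drop(outer(x, 0:4, `^`) %*% co)
  ft <- fit_trajectory(x, y, 4)
  expect_equal(ft$coefficients, co, tolerance = 1e-8)
  expect_equal(ft$r2, 1)
  expect_equal(ft$adj_r2, 1)
  expect_error(fit_trajectory(0:4, rnorm(5), 4), "degree \\+ 2")
})

test_that("adjusted R-squared follows its definitional formula", {
  # construct n = 7 data with R^2 exactly 0.97: quartic signal plus a
  # residual orthogonal to the polynomial space, scaled to SSres/SStot = 0.03
  x <- 0:6
  y0 <- 1 + 0.2 * x - 0.1 * x^2 + 0.03 * x^3 - 0.002 * x^4
  set.seed(12)
  e <- residuals(lm(rnorm(7) ~ poly(x, 4, raw = TRUE)))
  ss_tot0 <- function(r) sum((y0 + r - mean(y0 + r))^2)
  # solve for the residual scale giving the target ratio (1-d root find)
  f <- function(s) sum((s * e)^2) / ss_tot0(s * e) - 0.03
  s <- uniroot(f, c(1e-6, 50), tol = 1e-12)$root
  ft <- fit_trajectory(x, y0 + s * e, 4)
  expect_equal(ft$r2, 0.97, tolerance = 1e-6)
  expect_equal(ft$adj_r2, 1 - 0.03 * 6 / 2, tolerance = 1e-6)
  expect_equal(ft$adj_r2, 0.91, tolerance = 1e-6)
})

test_that("polynomial fits agree with explicit normal equations to 10 digits", {
  set.seed(13)
  for (i in 1:100) {
    x <- 0:6
    y <- rnorm(7, sd = 2)
    ft <- fit_trajectory(x, y, 4)
    X <- outer(x, 0:4, `^`)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(ft$coefficients, drop(beta), tolerance = 1e-10)
    expect_lte(ft$adj_r2, ft$r2 + 1e-12)
  }
})

test_that("quartic signal in mild noise is recovered within 3 sigma", {
  x <- 0:6
  co <- c(1, 0.3, -0.15, 0.04, -0.003)
  y0 <- drop(outer(x, 0:4, `^`) %*% co)
  sigma <- 0.02
  set.seed(14)
  ok <- 0; reps <- 1000
  for (i in 1:reps) {
    ft <- fit_trajectory(x, y0 + rnorm(7, 0, sigma), 4)
    if (max(abs(predict_trajectory(ft, x) - y0)) < 3 * sigma) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})

test_that("fit_trajectories fits per protein on condition means", {
  tb <- suppressMessages(normalize_to_reference(make_table()))
  res <- fit_trajectories(tb)
  expect_setequal(res$protein, c("PsaA", "PsbA"))
  expect_true(all(res$n == 7))
  expect_true(all(res$adj_r2 <= res$r2 + 1e-12))
  # with GL dropped there are 6 points for a 4th-degree fit
  res6 <- fit_trajectories(tb, drop_reference = TRUE)
  expect_true(all(res6$n == 6))
})

test_that("oligomer ratios handle identity, plain division and zero denominators", {
  bd <- band_table(data.frame(
    assembly = rep(c("PSI monomer", "PSI trimer"), each = 4),
    condition = rep(c("GL", "GL", "LL1", "LL1"), 2),
    replicate = rep(c(1, 2), 4),
    intensity = c(3, 3, 2, 4,  1, 1, 0, 2)))
  rt <- oligomer_ratios(bd)
  gl <- rt[rt$condition == "GL", ]
  expect_equal(gl$mean_ratio, 3)
  expect_false(gl$undefined)
  ll <- rt[rt$condition == "LL1", ]
  expect_true(ll$undefined)
  expect_true(is.na(ll$mean_ratio))
  # identity
  bd2 <- band_table(data.frame(assembly = rep(c("PSII monomer", "PSII dimer"), 2),
                               condition = "GL", replicate = rep(1:2, each = 2),
                               intensity = 5))
  rt2 <- oligomer_ratios(bd2)
  expect_equal(rt2$mean_ratio, 1)
  bd3 <- band_table(data.frame(assembly = c("PSI monomer", "PSI trimer", "PSI trimer"),
                               condition = "GL", replicate = c(1, 1, 2),
                               intensity = 1))
  expect_error(oligomer_ratios(bd3), "mismatched")
})
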