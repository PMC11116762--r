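make_drivers <- function(n = 15, seed = 1) {
  set.seed(seed)
  years <- 2000 + seq_len(n) - 1
  co2 <- 370 + 1.9 * seq_len(n) + rnorm(n, 0, 0.3)
  vp <- 8 + 0.02 * seq_len(n) + rnorm(n, 0, 0.4)
  tm <- 22 + 0.03 * seq_len(n) + rnorm(n, 0, 0.5)
  list(years = years, co2 = co2, vp = vp, tm = tm)
}

test_that("annual_drivers enforces alignment", {
  d <- make_drivers()
  expect_s3_class(annual_drivers(d$years, d$co2, d$co2, d$vp, d$tm),
                  "annual_drivers")
  expect_error(annual_drivers(c(2000, 2002, 2003), 1:3, 1:3, 1:3, 1:3),
               "step 1")
  expect_error(annual_drivers(d$years, d$co2[-1], d$co2, d$vp, d$tm),
               "match the year axis")
})

test_that("annualize aggregates monthly cubes with a missing-month budget", {
  v <- array(5, c(24, 2, 2))
  cube <- climate_cube(v, rep(2000:2001, each = 12), c(40, 50), c(0, 10),
                       "x", "u", months = rep(1:12, 2))
  expect_equal(annualize(cube, "mean")$values, array(5, c(2, 2, 2)))
  expect_equal(annualize(cube, "sum")$values, array(60, c(2, 2, 2)))

  # one missing month, tolerance 1: mean of the remaining 11
  v2 <- array(rep(1:24, 4), c(24, 2, 2))
  v2[5, 1, 1] <- NA
  cube2 <- climate_cube(v2, rep(2000:2001, each = 12), c(40, 50), c(0, 10),
                        "x", "u", months = rep(1:12, 2))
  a1 <- annualize(cube2, "mean", tolerance = 1)
  expect_equal(a1$values[1, 1, 1], mean((1:12)[-5]))
  expect_equal(a1$values[1, 2, 1], mean(1:12))
  # tolerance 0: that pixel-year is masked
  a0 <- annualize(cube2, "mean", tolerance = 0)
  expect_true(is.na(a0$values[1, 1, 1]))
  expect_false(is.na(a0$values[2, 1, 1]))

  expect_error(annualize(climate_cube(array(1, c(2, 1, 1)), 2000:2001,
                                      45, 0, "x", "u"), "mean"),
               "monthly")
})

test_that("fit_window interpolates a noiseless linear model exactly", {
  d <- make_drivers()
  gpp <- 0.5 * d$co2 + 2 * d$vp + 1 * d$tm + 10
  fw <- fit_window(annual_drivers(d$years, gpp, d$co2, d$vp, d$tm))
  expect_true(fw$valid)
  expect_equal(fw$beta_raw, 0.5, tolerance = 1e-8)
  expect_equal(fw$a1, 2, tolerance = 1e-8)
  expect_equal(fw$a2, 1, tolerance = 1e-8)
  expect_equal(fw$a3, 10, tolerance = 1e-8)
  expect_equal(fw$r_squared, 1, tolerance = 1e-10)
  # normalisation invariant
  expect_equal(fw$beta_rel, fw$beta_raw * 100 / mean(gpp) * 100)
})

test_that("fit_window agrees with the pseudo-inverse oracle", {
  set.seed(42)
  for (k in 1:50) {
    n <- sample(8:20, 1)
    X <- cbind(rnorm(n, 380, 10), rnorm(n, 8, 1), rnorm(n, 20, 2), 1)
    y <- rnorm(n, 1000, 50)
    years <- 2000 + seq_len(n) - 1
    fw <- fit_window(annual_drivers(years, y, X[, 1], X[, 2], X[, 3]))
    oracle <- pinv_ols(X, y)
    expect_equal(c(fw$beta_raw, fw$a1, fw$a2, fw$a3), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("degenerate designs are flagged invalid, not returned", {
  d <- make_drivers()
  gpp <- rnorm(15, 1000, 10)
  # constant CO2: collinear with the intercept
  fw <- fit_window(annual_drivers(d$years, gpp, rep(380, 15), d$vp, d$tm))
  expect_false(fw$valid)
  expect_true(is.na(fw$beta_rel))
  # masked year inside the window voids it
  gpp[7] <- NA
  fw2 <- fit_window(annual_drivers(d$years, gpp, d$co2, d$vp, d$tm))
  expect_false(fw2$valid)
  expect_error(fit_window(annual_drivers(d$years, gpp, d$co2, d$vp, d$tm),
                          years = 1999:2013), "not fully covered")
})

test_that("moving-window bookkeeping matches n - L + 1", {
  d <- make_drivers(n = 34)
  gpp <- 1000 + 0.5 * d$co2 + rnorm(34)
  dr <- annual_drivers(d$years, gpp, d$co2, d$vp, d$tm)
  mb <- moving_beta(dr, window_len = 15)
  expect_identical(nrow(mb), 20L)
  expect_identical(mb$window_center, d$years[8:27])
  expect_identical(nrow(moving_beta(dr, window_len = 34)), 1L)
  d15 <- make_drivers(n = 15)
  expect_identical(
    nrow(moving_beta(annual_drivers(d15$years, gpp[1:15], d15$co2, d15$vp,
                                    d15$tm))), 1L)
  expect_error(moving_beta(annual_drivers(d15$years, gpp[1:15], d15$co2,
                                          d15$vp, d15$tm), window_len = 16),
               "shorter")
  # stride 2 halves the window count
  expect_identical(nrow(moving_beta(dr, window_len = 15, stride = 2)), 10L)
})

test_that("beta_trend matches the closed-form slope and flags exact cases", {
  centers <- 1990:2009
  # exactly linear series
  bs <- data.frame(window_center = centers,
                   beta_rel = 5 - 0.01 * (centers - 1990), valid = TRUE)
  tr <- beta_trend(bs)
  expect_equal(tr$slope, -0.01, tolerance = 1e-12)
  expect_true(tr$significant)
  # constant series: zero slope, not significant
  bc <- data.frame(window_center = centers, beta_rel = 3, valid = TRUE)
  trc <- beta_trend(bc)
  expect_equal(trc$slope, 0)
  expect_false(trc$significant)
  # closed-form oracle on a noisy series
  set.seed(9)
  y <- 4 + 0.02 * centers + rnorm(20, 0, 0.3)
  bn <- data.frame(window_center = centers, beta_rel = y, valid = TRUE)
  expect_equal(beta_trend(bn)$slope, slope_oracle(centers, y),
               tolerance = 1e-10)
  # fewer than 3 valid windows: masked
  expect_true(is.na(beta_trend(bn[1:2, ])$slope))
})

test_that("shift and scale invariances of the window fit hold", {
  d <- make_drivers(seed = 5)
  set.seed(5)
  gpp <- 900 + 0.4 * d$co2 + rnorm(15, 0, 5)
  f0 <- fit_window(annual_drivers(d$years, gpp, d$co2, d$vp, d$tm))
  # adding a constant moves only the intercept
  f1 <- fit_window(annual_drivers(d$years, gpp + 250, d$co2, d$vp, d$tm))
  expect_equal(f1$beta_raw, f0$beta_raw, tolerance = 1e-10)
  expect_equal(f1$a1, f0$a1, tolerance = 1e-10)
  expect_equal(f1$a2, f0$a2, tolerance = 1e-10)
  expect_equal(f1$a3, f0$a3 + 250, tolerance = 1e-8)
  # scaling GPP scales beta_raw but cancels in beta_rel
  f2 <- fit_window(annual_drivers(d$years, 3 * gpp, d$co2, d$vp, d$tm))
  expect_equal(f2$beta_raw, 3 * f0$beta_raw, tolerance = 1e-10)
  expect_equal(f2$beta_rel, f0$beta_rel, tolerance = 1e-10)
})

test_that("a stationary sensitivity stays statistically constant", {
  scen <- generate_scenario(scenario_config(beta_rel_trend = 0, seed = 21))
  gb <- scenario_grid_beta(scen)
  bm <- apply(gb$beta_rel, 1, mean)
  fit <- summary(lm(bm ~ gb$window_center))
  ci <- confint(lm(bm ~ gb$window_center))[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})
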