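test_that("driver regression recovers exact coefficients and masks underdetermined pixels", {
  set.seed(3)
  n <- 20
  drv <- data.frame(VPD = rnorm(n), Wa = rnorm(n), Nit = rnorm(n),
                    Pho = rnorm(n))
  beta <- 2 * drv$VPD - 1 * drv$Wa
  fit <- fit_driver_regression(beta, drv)
  expect_true(fit$valid)
  expect_equal(unname(fit$coef[1:4]), c(2, -1, 0, 0), tolerance = 1e-8)

  # oracle agreement on random noisy inputs
  for (k in 1:25) {
    y <- rnorm(n)
    f <- fit_driver_regression(y, drv)
    oracle <- pinv_ols(cbind(as.matrix(drv), 1), y)
    expect_equal(unname(f$coef), unname(oracle), tolerance = 1e-8)
  }

  # fewer windows than parameters: masked
  f5 <- fit_driver_regression(beta[1:5], drv[1:5, ])
  expect_false(f5$valid)
  expect_true(all(is.na(f5$coef)))
  expect_error(fit_driver_regression(beta[1:10], drv), "match")
})

test_that("standardized coefficients follow |a| sd(x)/sd(beta)", {
  # sd(VPD)=1, sd(beta)=2, a1=2 -> Stc = 1
  base <- c(-1, 0, 1, -1, 0, 1)
  vpd_s <- base / sd(base)                        # sample sd exactly 1
  expect_equal(sd(vpd_s), 1)
  beta <- 2 * vpd_s
  stc <- standardized_coefficients(c(VPD = 2), data.frame(VPD = vpd_s), beta)
  expect_equal(unname(stc), 1)

  # constant driver contributes zero
  stc2 <- standardized_coefficients(c(VPD = 2, Wa = 5),
                                    data.frame(VPD = vpd_s, Wa = rep(3, 6)),
                                    beta)
  expect_equal(unname(stc2["Wa"]), 0)

  # unit rescaling of a driver leaves Stc unchanged
  set.seed(8)
  n <- 18
  drv <- data.frame(VPD = rnorm(n, 8, 1), Wa = rnorm(n, 20, 5))
  y <- 1.5 * drv$VPD - 0.2 * drv$Wa + rnorm(n, 0, 0.5)
  s1 <- standardized_coefficients(fit_driver_regression(y, drv)$coef, drv, y)
  drv2 <- transform(drv, Wa = Wa * 1000)
  s2 <- standardized_coefficients(fit_driver_regression(y, drv2)$coef, drv2, y)
  expect_equal(s1, s2, tolerance = 1e-10)

  # constant beta: undefined
  expect_true(all(is.na(
    standardized_coefficients(c(VPD = 2), data.frame(VPD = vpd_s),
                              rep(1, 6)))))
})

test_that("relative contributions normalise to one", {
  expect_equal(unname(relative_contributions(c(a = 2, b = 1, c = 1, d = 0))),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(relative_contributions(c(a = 1, b = 0, c = 0, d = 0))),
               c(1, 0, 0, 0))
  expect_true(all(is.na(relative_contributions(c(a = 0, b = 0)))))
  # permuting driver order permutes outputs correspondingly
  stc <- c(VPD = 3, Wa = 2, Nit = 1)
  perm <- c("Nit", "VPD", "Wa")
  expect_identical(relative_contributions(stc)[perm],
                   relative_contributions(stc[perm]))
})

test_that("partial correlations match the two-stage residual oracle", {
  set.seed(11)
  n <- 30
  d1 <- rnorm(n); d2 <- rnorm(n); d3 <- rnorm(n)
  beta <- d1 + 0.001 * rnorm(n)   # essentially driver 1
  pc <- partial_correlation_contribution(beta,
                                         data.frame(d1 = d1, d2 = d2))
  expect_gt(pc$r_partial[1], 0.99)
  expect_lt(abs(pc$r_partial[2]), 0.2)
  expect_gt(pc$share[1], 0.8)

  # oracle: residual-on-residual via lm
  y <- 0.5 * d1 - 0.8 * d2 + 0.3 * d3 + rnorm(n)
  drv <- data.frame(d1 = d1, d2 = d2, d3 = d3)
  pc2 <- partial_correlation_contribution(y, drv)
  for (j in 1:3) {
    others <- drv[, -j, drop = FALSE]
    ry <- residuals(lm(y ~ ., data = others))
    rx <- residuals(lm(drv[[j]] ~ ., data = others))
    expect_equal(pc2$r_partial[j], cor(ry, rx), tolerance = 1e-10)
  }
  expect_equal(sum(pc2$share), 1, tolerance = 1e-12)

  # duplicated driver: perfect collinearity among controls -> masked
  pc3 <- partial_correlation_contribution(y, data.frame(d1 = d1, d1b = d1,
                                                        d2 = d2))
  expect_true(all(is.na(pc3$r_partial)))
})

test_that("gridded attribution recovers generating shares exactly without noise", {
  sc <- generate_attribution_scenario(noise_sd = 0, seed = 5)
  ct <- attribute_grid(sc$beta_field, sc$driver_fields)
  expect_true(all(ct$valid))
  # contributions equal the generating shares in every pixel
  for (x in names(sc$shares))
    expect_equal(max(abs(ct$contrib[x, , ] - sc$shares[[x]])), 0,
                 tolerance = 1e-10)
  # sum-to-one and non-negativity, exact per construction
  sums <- apply(ct$contrib, c(2, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  expect_true(all(ct$contrib >= 0))
})

test_that("regional contribution summaries weight by area and can pool nutrients", {
  sc <- generate_attribution_scenario(noise_sd = 0.15, n_lat = 2, n_lon = 2,
                                      seed = 2)
  ct <- attribute_grid(sc$beta_field, sc$driver_fields)
  lat <- c(0, 60)
  sm <- regional_contribution_summary(ct, lat)
  # hand-computed cos-latitude weighted mean for one driver on the 2x2 grid
  w <- cos_lat_weights(lat, 2)
  v <- matrix(ct$contrib["VPD", , ], 2, 2)
  expect_equal(sm$mean_contribution[sm$driver == "VPD"],
               sum(v * w) / sum(w), tolerance = 1e-12)

  # single pixel: mean equals the pixel, zero spread
  region <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  s1 <- regional_contribution_summary(ct, lat, region = region)
  expect_equal(s1$mean_contribution[s1$driver == "VPD"], v[1, 1])
  expect_equal(s1$spread, rep(0, 4))

  # pooled nutrients mirror the VPD / water / nutrient partition
  sp <- regional_contribution_summary(ct, lat, pool_nutrients = TRUE)
  expect_setequal(sp$driver, c("VPD", "Wa", "nutrient"))
  expect_equal(sum(sp$mean_contribution), 1, tolerance = 1e-10)

  expect_error(regional_contribution_summary(ct, lat,
                                             region = matrix(FALSE, 2, 2)),
               "empty")
})

test_that("window means align drivers with the beta window axis", {
  v <- array(rep(1:20, 4), c(20, 2, 2))
  wm <- window_means(v, window_len = 15)
  expect_identical(dim(wm), c(6L, 2L, 2L))
  expect_equal(wm[1, 1, 1], mean(1:15))
  expect_equal(wm[6, 2, 2], mean(6:20))
  expect_error(window_means(v[1:10, , , drop = FALSE], window_len = 15),
               "shorter")
})
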