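# Independent oracles kept deliberately separate from the package internals.

# Pseudo-inverse OLS: coefficients via SVD pinv of X, the closed-form
# normal-equations solution. Independent of the package's QR path.
pinv_ols <- function(X, y) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1L]
  coef <- s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep])
  drop(coef)
}

# Closed-form simple-regression slope.
slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Driver noise switched off entirely.
zero_driver_noise <- list(tas = 0, rh = 0, tmax = 0, precip = 0, et = 0,
                          ndep = 0, pdep = 0)

quiet_scenario <- function(seed = 1L, ...) {
  generate_scenario(scenario_config(noise_sd_gpp = 0,
                                    noise_sd_drivers = zero_driver_noise,
                                    seed = seed, ...))
}

# Full grid moving-window estimate from a generated scenario.
scenario_grid_beta <- function(scen, ...) {
  vc <- vpd_cube(scen$cubes$tas, rh = scen$cubes$rh)
  grid_moving_beta(scen$cubes$gpp, vc, scen$cubes$tmax, scen$co2, ...)
}
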