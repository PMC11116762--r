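#' Driver regression for the sensitivity decline
#'
#' Multiple OLS regression of a pixel's windowed sensitivity series
#' \eqn{\beta_m} on co-windowed driver series (VPD, water availability
#' = precipitation - ET, N deposition, P deposition, or any subset):
#' \deqn{\beta_m = a_{1m} VPD_m + a_{2m} Wa_m + a_{3m} Nit_m + a_{4m} Pho_m + \varepsilon}
#' An intercept is always included (without it the contributions would
#' absorb mean offsets). Requires at least `k + 2` windows for `k` drivers;
#' rank-deficient designs mask the pixel.
#'
#' @param beta_series numeric vector of windowed sensitivity values.
#' @param drivers data.frame or named list of driver series, each the same
#'   length as `beta_series` (windowed means on the same window axis).
#' @param cond_tol condition-number threshold flagging unstable fits.
#' @return A list: `coef` (named, drivers then `"(intercept)"`),
#'   `residuals`, `valid`.
#' @export
fit_driver_regression <- function(beta_series, drivers, cond_tol = 1e8) {
  drivers <- as.data.frame(drivers)
  k <- ncol(drivers)
  n <- length(beta_series)
  if (any(vapply(drivers, length, 1L) != n))
    stop("driver series must match the beta window axis", call. = FALSE)
  out <- list(coef = stats::setNames(rep(NA_real_, k + 1L),
                                     c(names(drivers), "(intercept)")),
              residuals = rep(NA_real_, n), valid = FALSE)
  ok <- stats::complete.cases(beta_series, drivers)
  if (sum(ok) < k + 2L) return(out)
  X <- cbind(as.matrix(drivers[ok, , drop = FALSE]), `(intercept)` = 1)
  fit <- ols_fit(X, beta_series[ok], cond_tol = cond_tol)
  if (!fit$valid) return(out)
  out$coef[] <- fit$coef
  out$residuals[ok] <- fit$residuals
  out$valid <- TRUE
  out
}

#' Standardized driver coefficients
#'
#' Rescales each driver's regression coefficient by the ratio of its standard
#' deviation to that of the sensitivity series:
#' \deqn{Stc_X = |a_X| \cdot sd(X) / sd(\beta)}
#' so drivers in different units become comparable. Absolute values are taken
#' so the downstream contributions are non-negative; the signed coefficients
#' remain available from [fit_driver_regression()]. A driver that is constant
#' over the windows (sd = 0) gets Stc = 0; a constant sensitivity series
#' (sd(\eqn{\beta}) = 0) leaves the pixel undefined.
#'
#' @param coef named coefficient vector from [fit_driver_regression()]
#'   (the intercept entry, if present, is ignored).
#' @param drivers the driver data used in the fit.
#' @param beta_series the sensitivity series used in the fit.
#' @return Named vector of standardized coefficients, or all-`NA` if
#'   undefined.
#' @export
standardized_coefficients <- function(coef, drivers, beta_series) {
  drivers <- as.data.frame(drivers)
  nm <- names(drivers)
  a <- coef[nm]
  sdb <- stats::sd(beta_series, na.rm = TRUE)
  if (!is.finite(sdb) || sdb == 0)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  sdx <- vapply(drivers, stats::sd, numeric(1L), na.rm = TRUE)
  stats::setNames(abs(a) * sdx / sdb, nm)
}

#' Relative driver contributions
#'
#' Normalises standardized coefficients to fractions summing to one:
#' \deqn{R_X = Stc_X \,/\, \sum_Y Stc_Y.}
#' All-zero (or undefined) standardized coefficients leave the pixel masked.
#'
#' @param stc named vector of standardized coefficients (non-negative).
#' @return Named vector of contributions in \[0, 1\] summing to 1, or
#'   all-`NA` when undefined.
#' @export
relative_contributions <- function(stc) {
  if (anyNA(stc) || sum(stc) <= 0)
    return(stats::setNames(rep(NA_real_, length(stc)), names(stc)))
  stc / sum(stc)
}

#' Partial-correlation driver shares
#'
#' Cross-check on the standardized-coefficient scheme: the partial
#' correlation of the sensitivity series with each driver, controlling for
#' all the others by the residual-on-residual method (correlate the
#' residuals of \eqn{\beta} ~ others with the residuals of X ~ others).
#' Shares are the absolute partial correlations normalised across drivers.
#' Useful for separating VPD from temperature, whose effects overlap because
#' VPD is computed from temperature.
#'
#' @param beta_series numeric vector of windowed sensitivity values (>= 5
#'   windows required).
#' @param drivers data.frame/list of driver series (may include temperature
#'   alongside VPD).
#' @return A data.frame: `driver`, `r_partial` (signed), `share`
#'   (normalised |r|). All-`NA` rows when a control regression is singular.
#' @export
partial_correlation_contribution <- function(beta_series, drivers) {
  drivers <- as.data.frame(drivers)
  nm <- names(drivers)
  k <- ncol(drivers)
  out <- data.frame(driver = nm, r_partial = NA_real_, share = NA_real_)
  ok <- stats::complete.cases(beta_series, drivers)
  if (sum(ok) < max(5L, k + 2L)) return(out)
  y <- beta_series[ok]
  D <- as.matrix(drivers[ok, , drop = FALSE])
  r <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    Z <- cbind(D[, -j, drop = FALSE], 1)
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) return(out)  # perfect collinearity among controls
    ry <- stats::lm.fit(Z, y)$residuals
    rx <- stats::lm.fit(Z, D[, j])$residuals
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(out)
    r[j] <- stats::cor(rx, ry)
  }
  out$r_partial <- r
  out$share <- abs(r) / sum(abs(r))
  out
}

#' Pixel-wise attribution over a grid
#'
#' Runs [fit_driver_regression()], [standardized_coefficients()] and
#' [relative_contributions()] in every pixel of a gridded windowed
#' sensitivity field against co-windowed driver fields.
#'
#' @param beta_field array `(window, lat, lon)` of windowed sensitivity
#'   values.
#' @param driver_fields named list of arrays with the same shape, one per
#'   driver (historical mode: VPD, Wa, Nit, Pho; future mode: VPD, Wa,
#'   soil N).
#' @param cond_tol passed to the per-pixel fit.
#' @return A `contribution_table`: list with `coef`, `stc`, `contrib`
#'   (arrays `(driver, lat, lon)`), `drivers` (names), `valid` matrix.
#' @export
attribute_grid <- function(beta_field, driver_fields, cond_tol = 1e8) {
  nm <- names(driver_fields)
  stopifnot(length(nm) >= 1L, all(nzchar(nm)))
  d <- dim(beta_field)
  for (f in driver_fields)
    if (!identical(dim(f), d))
      stop("driver fields must share the beta field's shape", call. = FALSE)
  k <- length(nm)
  coef_a <- stc_a <- con_a <- array(NA_real_, c(k, d[2L], d[3L]),
                                    dimnames = list(nm, NULL, NULL))
  valid <- matrix(FALSE, d[2L], d[3L])
  for (i in seq_len(d[2L])) for (j in seq_len(d[3L])) {
    b <- beta_field[, i, j]
    dd <- as.data.frame(lapply(driver_fields, function(f) f[, i, j]))
    names(dd) <- nm
    fit <- fit_driver_regression(b, dd, cond_tol = cond_tol)
    if (!fit$valid) next
    stc <- standardized_coefficients(fit$coef, dd, b)
    con <- relative_contributions(stc)
    coef_a[, i, j] <- fit$coef[nm]
    stc_a[, i, j] <- stc
    con_a[, i, j] <- con
    valid[i, j] <- !anyNA(con)
  }
  structure(list(coef = coef_a, stc = stc_a, contrib = con_a,
                 drivers = nm, valid = valid),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat(sprintf("<contribution_table> drivers: %s; %d / %d valid pixels\n",
              paste(x$drivers, collapse = ", "), sum(x$valid),
              length(x$valid)))
  invisible(x)
}

#' Regional summary of driver contributions
#'
#' Area-weighted regional mean contribution per driver plus the across-pixel
#' spread (weighted standard deviation). Nutrient drivers can be pooled
#' (N + P reported as one "nutrient" category) to mirror the usual
#' VPD / water / nutrients partition.
#'
#' @param ct a `contribution_table` from [attribute_grid()].
#' @param lat latitude vector of the grid (for cos-latitude weights).
#' @param region optional logical `(lat, lon)` inclusion matrix.
#' @param pool_nutrients sum the `Nit` and `Pho` rows into one `nutrient`
#'   category (no-op when absent)?
#' @param weighted area weighting (default) or plain averaging.
#' @return A data.frame: `driver`, `mean_contribution`, `spread`, `n_pixels`.
#' @export
regional_contribution_summary <- function(ct, lat, region = NULL,
                                          pool_nutrients = FALSE,
                                          weighted = TRUE) {
  stopifnot(inherits(ct, "contribution_table"))
  con <- ct$contrib
  nm <- ct$drivers
  if (pool_nutrients && all(c("Nit", "Pho") %in% nm)) {
    keep <- setdiff(nm, c("Nit", "Pho"))
    pooled <- con["Nit", , , drop = FALSE] + con["Pho", , , drop = FALSE]
    con <- abind_first(con[keep, , , drop = FALSE], pooled, "nutrient")
    nm <- c(keep, "nutrient")
  }
  nlat <- dim(con)[2L]; nlon <- dim(con)[3L]
  ok <- ct$valid
  if (!is.null(region)) ok <- ok & region
  if (!any(ok)) stop("empty region: no valid pixels", call. = FALSE)
  w <- if (weighted) cos_lat_weights(lat, nlon) else matrix(1, nlat, nlon)
  rows <- lapply(seq_along(nm), function(r) {
    v <- matrix(con[r, , ], nlat, nlon)
    m <- sum(v[ok] * w[ok]) / sum(w[ok])
    s <- sqrt(sum(w[ok] * (v[ok] - m)^2) / sum(w[ok]))
    data.frame(driver = nm[r], mean_contribution = m, spread = s,
               n_pixels = sum(ok))
  })
  do.call(rbind, rows)
}

#' @keywords internal
#' Bind one extra named slice onto the first (driver) axis of a 3-d array.
abind_first <- function(a, slice, name) {
  d <- dim(a)
  out <- array(NA_real_, c(d[1L] + 1L, d[2L], d[3L]),
               dimnames = list(c(dimnames(a)[[1L]], name), NULL, NULL))
  out[seq_len(d[1L]), , ] <- a
  out[d[1L] + 1L, , ] <- slice
  out
}

#' Windowed driver means on the moving-window axis
#'
#' Averages an annual per-pixel field over the same fixed-length moving
#' windows used for the sensitivity estimates, so drivers and sensitivity
#' share a window axis before attribution.
#'
#' @param values array `(year, lat, lon)` of annual values (or a
#'   `climate_cube`).
#' @param window_len,stride window geometry (defaults 15, 1).
#' @return Array `(window, lat, lon)` of window means.
#' @export
window_means <- function(values, window_len = 15L, stride = 1L) {
  if (inherits(values, "climate_cube")) values <- values$values
  n <- dim(values)[1L]
  if (n < window_len)
    stop("series shorter than the window", call. = FALSE)
  starts <- seq(1L, n - window_len + 1L, by = stride)
  out <- array(NA_real_, c(length(starts), dim(values)[2L], dim(values)[3L]))
  for (s in seq_along(starts)) {
    idx <- starts[s]:(starts[s] + window_len - 1L)
    out[s, , ] <- apply(values[idx, , , drop = FALSE], c(2L, 3L), mean)
  }
  out
}
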