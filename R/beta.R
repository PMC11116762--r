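#' @keywords internal
#' OLS with diagnostics via QR, shared by the window fits, driver-attribution
#' fits and trend maps. X must already include an intercept column if wanted.
#' Returns NULL-free list; `valid` is FALSE on rank deficiency or when the
#' design's condition number exceeds `cond_tol`.
ols_fit <- function(X, y, cond_tol = 1e8) {
  n <- nrow(X); p <- ncol(X)
  out <- list(coef = rep(NA_real_, p), se = rep(NA_real_, p),
              p_value = rep(NA_real_, p), r_squared = NA_real_,
              sigma2 = NA_real_, condition_number = NA_real_,
              residuals = rep(NA_real_, n), valid = FALSE, n = n)
  if (n < p) return(out)
  sv <- svd(X, nu = 0, nv = 0)$d
  out$condition_number <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  qr_x <- qr(X)
  if (qr_x$rank < p || out$condition_number > cond_tol) return(out)
  coef <- qr.coef(qr_x, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  df <- n - p
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  pv <- if (df > 0) 2 * stats::pt(abs(coef / se), df, lower.tail = FALSE)
        else rep(NA_real_, p)
  out$coef <- coef; out$se <- se; out$p_value <- pv
  out$r_squared <- if (tss > 0) 1 - rss / tss else NA_real_
  out$sigma2 <- sigma2
  out$residuals <- res
  out$valid <- TRUE
  out
}

#' Aligned annual driver series for one pixel
#'
#' Bundles the co-registered annual series entering the sensitivity
#' regression: GPP, the (shared) atmospheric CO2 series, VPD and maximum
#' temperature. Years must be strictly increasing with step 1 and all series
#' must share the year axis.
#'
#' @param years integer calendar years, strictly increasing, step 1.
#' @param gpp annual gross primary production (any self-consistent flux unit).
#' @param co2 annual atmospheric CO2, ppm.
#' @param vpd annual vapor pressure deficit, hPa.
#' @param tmax annual maximum temperature, degrees C.
#' @return An object of class `annual_drivers`.
#' @export
annual_drivers <- function(years, gpp, co2, vpd, tmax) {
  years <- as.integer(years)
  n <- length(years)
  if (n >= 2L && !all(diff(years) == 1L))
    stop("years must be strictly increasing with step 1", call. = FALSE)
  lens <- c(length(gpp), length(co2), length(vpd), length(tmax))
  if (any(lens != n))
    stop("all driver series must match the year axis (", n, " years)",
         call. = FALSE)
  structure(list(years = years, gpp = as.numeric(gpp), co2 = as.numeric(co2),
                 vpd = as.numeric(vpd), tmax = as.numeric(tmax)),
            class = "annual_drivers")
}

#' Collapse a monthly cube to annual values
#'
#' Aggregates the 12 monthly slices of each calendar year to one annual value
#' per pixel (`mean`, `sum` or `max`). A year missing more months than
#' `tolerance` (per pixel) is masked; with fewer missing months the statistic
#' is computed from the months present (for `sum`, rescaled by 12/m so annual
#' totals stay comparable).
#'
#' @param cube monthly `climate_cube` (must carry a `months` axis).
#' @param how one of `"mean"`, `"sum"`, `"max"`.
#' @param tolerance maximum number of missing months tolerated per year.
#' @return An annual `climate_cube`; the aggregation method is recorded in the
#'   units string metadata suffix.
#' @export
annualize <- function(cube, how = c("mean", "sum", "max"), tolerance = 0L) {
  stopifnot(inherits(cube, "climate_cube"))
  how <- match.arg(how)
  if (is.null(cube$months))
    stop("cube has no monthly time axis; nothing to annualize", call. = FALSE)
  yrs <- sort(unique(cube$years))
  nlat <- length(cube$lat); nlon <- length(cube$lon)
  out <- array(NA_real_, c(length(yrs), nlat, nlon))
  for (i in seq_along(yrs)) {
    idx <- which(cube$years == yrs[i])
    slab <- cube$values[idx, , , drop = FALSE]
    nmiss <- apply(is.na(slab), c(2L, 3L), sum) + (12L - length(idx))
    agg <- switch(how,
      mean = apply(slab, c(2L, 3L), mean, na.rm = TRUE),
      max  = apply(slab, c(2L, 3L), max,  na.rm = TRUE),
      sum  = {
        s <- apply(slab, c(2L, 3L), sum, na.rm = TRUE)
        npres <- dim(slab)[1L] - apply(is.na(slab), c(2L, 3L), sum)
        ifelse(npres > 0, s * 12 / npres, NA_real_)
      })
    agg[!is.finite(agg) | nmiss > tolerance] <- NA_real_
    out[i, , ] <- agg
  }
  climate_cube(out, yrs, cube$lat, cube$lon, cube$varname,
               paste0(cube$units, " (annual ", how, ")"))
}

#' Fit the CO2-sensitivity regression in one window
#'
#' Ordinary least squares of annual GPP on CO2, VPD and maximum temperature
#' with an intercept,
#' \deqn{GPP_t = \beta\, CO2_t + a_1\, VPD_t + a_2\, T_{max,t} + a_3 + \varepsilon_t,}
#' the Gaussian maximum-likelihood solution. The raw CO2 coefficient
#' \eqn{\beta} (GPP units per ppm) is normalised to a relative sensitivity in
#' percent per 100 ppm via the window-mean GPP:
#' \deqn{\beta_{rel} = \beta \times 100\,\mathrm{ppm} / \overline{GPP} \times 100\%.}
#'
#' Rank-deficient or ill-conditioned designs (condition number above
#' `cond_tol`; CO2, VPD and Tmax all trend upward and can be near-collinear
#' in short windows) are flagged invalid rather than silently returned.
#'
#' @param drivers an [annual_drivers()] object.
#' @param years optional integer vector selecting the window (default: all
#'   years in `drivers`); must be fully covered by the series.
#' @param cond_tol condition-number threshold for flagging unstable fits.
#' @return An object of class `beta_estimate`: `beta_raw`, `beta_rel`,
#'   `a1` (VPD), `a2` (Tmax), `a3` (intercept), `r_squared`, `p_beta`,
#'   `window_center`, `n_used`, `condition_number`, `valid`.
#' @export
fit_window <- function(drivers, years = NULL, cond_tol = 1e8) {
  stopifnot(inherits(drivers, "annual_drivers"))
  if (is.null(years)) years <- drivers$years
  idx <- match(years, drivers$years)
  if (anyNA(idx))
    stop("window years not fully covered by the driver series", call. = FALSE)
  gpp <- drivers$gpp[idx]; co2 <- drivers$co2[idx]
  vp <- drivers$vpd[idx];  tm <- drivers$tmax[idx]
  center <- floor(stats::median(years))
  est <- list(beta_raw = NA_real_, beta_rel = NA_real_, a1 = NA_real_,
              a2 = NA_real_, a3 = NA_real_, r_squared = NA_real_,
              p_beta = NA_real_, window_center = center,
              n_used = 0L, condition_number = NA_real_, valid = FALSE)
  class(est) <- "beta_estimate"
  ok <- stats::complete.cases(gpp, co2, vp, tm)
  if (!all(ok)) return(est)  # any masked year voids the window
  X <- cbind(co2 = co2, vpd = vp, tmax = tm, intercept = 1)
  fit <- ols_fit(X, gpp, cond_tol = cond_tol)
  est$n_used <- fit$n
  est$condition_number <- fit$condition_number
  if (!fit$valid) return(est)
  mg <- mean(gpp)
  est$beta_raw <- fit$coef[[1L]]
  est$beta_rel <- if (mg != 0) fit$coef[[1L]] * 100 / mg * 100 else NA_real_
  est$a1 <- fit$coef[[2L]]; est$a2 <- fit$coef[[3L]]; est$a3 <- fit$coef[[4L]]
  est$r_squared <- fit$r_squared
  est$p_beta <- fit$p_value[[1L]]
  est$valid <- TRUE
  est
}

#' @export
print.beta_estimate <- function(x, ...) {
  cat(sprintf("<beta_estimate> window center %d (n=%d)%s\n", x$window_center,
              x$n_used, if (x$valid) "" else " [INVALID FIT]"))
  if (x$valid)
    cat(sprintf("  beta_rel = %.4f %% per 100 ppm  (raw %.4g, p = %.3g, R2 = %.3f)\n",
                x$beta_rel, x$beta_raw, x$p_beta, x$r_squared))
  invisible(x)
}

#' Moving-window sensitivity estimates
#'
#' Re-estimates [fit_window()] over fixed-length sliding windows (default 15
#' years, stride 1), labelling each window by its centre year. A series of
#' `n` years yields `n - window_len + 1` windows at stride 1.
#'
#' @param drivers an [annual_drivers()] object.
#' @param window_len window length in years (default 15).
#' @param stride step between window starts (default 1).
#' @param cond_tol passed to [fit_window()].
#' @return A data.frame with one row per window and the `beta_estimate`
#'   fields as columns.
#' @export
moving_beta <- function(drivers, window_len = 15L, stride = 1L,
                        cond_tol = 1e8) {
  stopifnot(inherits(drivers, "annual_drivers"))
  n <- length(drivers$years)
  if (n < window_len)
    stop("series (", n, " years) shorter than the window (", window_len, ")",
         call. = FALSE)
  starts <- seq(1L, n - window_len + 1L, by = stride)
  rows <- lapply(starts, function(s) {
    est <- fit_window(drivers, drivers$years[s:(s + window_len - 1L)],
                      cond_tol = cond_tol)
    as.data.frame(unclass(est))
  })
  do.call(rbind, rows)
}

#' Linear trend of a windowed sensitivity series
#'
#' OLS slope of `beta_rel` against window-centre year with a two-sided
#' t-test on the slope (n-2 degrees of freedom) and a significance flag at
#' the requested level. Fewer than 3 valid windows yields a masked result.
#'
#' @param beta_series data.frame from [moving_beta()] (needs `window_center`,
#'   `beta_rel`, `valid`).
#' @param alpha significance level (default 0.05).
#' @return A one-row data.frame: `slope` (percent per 100 ppm per year),
#'   `p_value`, `significant`, `n_windows`.
#' @export
beta_trend <- function(beta_series, alpha = 0.05) {
  ok <- beta_series$valid & is.finite(beta_series$beta_rel)
  x <- beta_series$window_center[ok]
  y <- beta_series$beta_rel[ok]
  tr <- slope_test(x, y, alpha = alpha)
  data.frame(slope = tr$slope, p_value = tr$p_value,
             significant = tr$significant, n_windows = length(x))
}

#' @keywords internal
#' Simple-regression slope with t-test; the single trend engine behind
#' beta_trend() and pixel_trend_map(). Returns NA-masked output for n < 3
#' or a degenerate x axis.
slope_test <- function(x, y, alpha = 0.05) {
  out <- list(slope = NA_real_, p_value = NA_real_, significant = NA)
  n <- length(x)
  if (n < 3L) return(out)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(out)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  rss <- sum(res^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  pv <- if (se == 0) {
    if (b == 0) 1 else 0   # exact fit: slope either exactly 0 or exact signal
  } else 2 * stats::pt(abs(b / se), df, lower.tail = FALSE)
  list(slope = b, p_value = pv, significant = pv < alpha)
}
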