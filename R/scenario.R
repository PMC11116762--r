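#' Configuration of a synthetic gridded scenario
#'
#' Describes the stated world the generator emulates: a near-linear CO2 rise,
#' a warming trend whose combination with a mildly drying relative humidity
#' drives a VPD increase of order 0.013 hPa per year, a GPP field whose
#' relative sensitivity to CO2 declines linearly through time, N deposition
#' rising until a break year and declining after it, slightly rising P
#' deposition, and precipitation rising faster than evapotranspiration.
#'
#' Deterministic quasi-periodic interannual variability (incommensurate sine
#' terms with per-pixel phases) is built into the meteorological fields so
#' the regression design stays full-rank even at zero noise; Gaussian noise
#' is added on top, controlled by `noise_sd_gpp` (fraction of mean GPP) and
#' `noise_sd_drivers`.
#'
#' @param n_lat,n_lon grid size (>= 1).
#' @param lat_range latitude span, degrees north (default 30-90, the
#'   northern middle and high latitudes).
#' @param year_start,year_end simulated calendar years (span must cover at
#'   least one 15-year window).
#' @param co2_start CO2 at `year_start`, ppm.
#' @param co2_rate CO2 growth, ppm per year.
#' @param beta_rel_start generating relative sensitivity at `year_start`,
#'   percent per 100 ppm.
#' @param beta_rel_trend linear change of the generating sensitivity,
#'   percent per 100 ppm per year.
#' @param tas_trend warming trend, degrees C per year.
#' @param rh_trend relative-humidity trend, percent per year (negative so
#'   VPD rises under warming).
#' @param precip_trend,et_trend water-balance trends, mm per month per year.
#' @param ndep_breakyear year after which N deposition declines.
#' @param noise_sd_gpp GPP noise standard deviation as a fraction of the
#'   pixel's mean GPP.
#' @param noise_sd_drivers named list of per-driver noise standard
#'   deviations (tas, rh, tmax, precip, et, ndep, pdep), in the driver's
#'   units.
#' @param gpp_vpd_coef,gpp_tmax_coef generating linear GPP responses to VPD
#'   and Tmax (GPP units per hPa / per degree C). Kept modest (about 0.5% of
#'   baseline GPP per hPa) so the slow drift these confounder terms impose
#'   on the window-mean GPP normalisation stays an order of magnitude below
#'   the sensitivity-trend signal; see the methods vignette.
#' @param co2_coupling `"exponential"` (default; the sensitivity is a true
#'   relative growth rate, consistent with its normalisation by window-mean
#'   GPP) or `"linear"` (GPP exactly linear in CO2 at constant sensitivity;
#'   used for exact-interpolation diagnostics).
#' @param seed master seed; all substreams derive from it, and an identical
#'   seed plus config reproduces the cubes bit for bit.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_lat = 10L, n_lon = 10L, lat_range = c(30, 90),
                            year_start = 1982L, year_end = 2015L,
                            co2_start = 341, co2_rate = 1.9,
                            beta_rel_start = 20, beta_rel_trend = -0.05,
                            tas_trend = 0.03, rh_trend = -0.05,
                            precip_trend = 0.044, et_trend = 0.02,
                            ndep_breakyear = 1990L,
                            noise_sd_gpp = 0.02,
                            noise_sd_drivers = list(tas = 0.3, rh = 1,
                                                    tmax = 0.4, precip = 2,
                                                    et = 1, ndep = 20,
                                                    pdep = 2),
                            gpp_vpd_coef = -6, gpp_tmax_coef = -1.5,
                            co2_coupling = c("exponential", "linear"),
                            seed = 1L) {
  co2_coupling <- match.arg(co2_coupling)
  cfg <- list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
              lat_range = lat_range,
              year_start = as.integer(year_start),
              year_end = as.integer(year_end),
              co2_start = co2_start, co2_rate = co2_rate,
              beta_rel_start = beta_rel_start,
              beta_rel_trend = beta_rel_trend,
              tas_trend = tas_trend, rh_trend = rh_trend,
              precip_trend = precip_trend, et_trend = et_trend,
              ndep_breakyear = as.integer(ndep_breakyear),
              noise_sd_gpp = noise_sd_gpp,
              noise_sd_drivers = noise_sd_drivers,
              gpp_vpd_coef = gpp_vpd_coef, gpp_tmax_coef = gpp_tmax_coef,
              co2_coupling = co2_coupling,
              seed = as.integer(seed))
  n_years <- cfg$year_end - cfg$year_start + 1L
  if (n_years < 15L)
    stop("scenario spans ", n_years,
         " years; at least one 15-year window is required", call. = FALSE)
  if (cfg$n_lat < 1L || cfg$n_lon < 1L)
    stop("grid dimensions must be >= 1", call. = FALSE)
  if (cfg$noise_sd_gpp < 0 || any(unlist(cfg$noise_sd_drivers) < 0))
    stop("noise scales must be non-negative", call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

#' @keywords internal
#' Deterministic per-variable RNG substream: the master seed is combined
#' with a name hash so each variable draws from its own reproducible stream
#' regardless of generation order. Kept below 2^31.
rng_substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  set.seed((abs(seed) * 7919L + h) %% 2147483647L)
}

#' Generate a synthetic scenario with known ground truth
#'
#' Builds co-registered annual cubes of GPP, air temperature, maximum
#' temperature, relative humidity, precipitation, evapotranspiration, N and P
#' deposition, plus a scalar CO2 series, with the statistical structure the
#' sensitivity analysis assumes. GPP is constructed around each pixel's
#' baseline \eqn{G_0}:
#' \deqn{GPP_t = G_0\, e^{F_t} + c_1 VPD'_t + c_2 T'_{max,t} + \epsilon_t}
#' where \eqn{F_t} is the trapezoid-accumulated relative growth
#' \eqn{\sum \beta_{true}(s)/10^4\, \Delta CO2_s} and primes denote
#' departures from the year-start state. With a linear CO2 ramp the moving-window
#' OLS recovers \eqn{\beta_{true}} at the window centre (exponential
#' coupling keeps the window-mean-GPP normalisation consistent with a
#' relative sensitivity); in `co2_coupling = "linear"` mode
#' (\eqn{G_0 (1 + F_t)}) noise-free GPP at constant sensitivity
#' interpolates the regression model exactly, so the generating raw
#' coefficients are recovered to machine precision.
#'
#' @param config a [scenario_config()].
#' @return A list with elements
#'   \describe{
#'     \item{cubes}{named list of annual `climate_cube`s: `gpp`, `tas`,
#'       `tmax`, `rh`, `precip`, `et`, `ndep`, `pdep`.}
#'     \item{co2}{data.frame `year`, `ppm`.}
#'     \item{truth}{ground truth: `beta_rel_true` array `(year, lat, lon)`,
#'       `coef_vpd`/`coef_tmax` matrices `(lat, lon)`, `baseline_gpp`
#'       matrix, and the config.}
#'   }
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  years <- cfg$year_start:cfg$year_end
  ny <- length(years)
  t_rel <- years - cfg$year_start
  lat <- seq(cfg$lat_range[1L], cfg$lat_range[2L], length.out = cfg$n_lat)
  if (cfg$n_lat == 1L) lat <- mean(cfg$lat_range)
  lon <- seq(-180, 180 - 360 / cfg$n_lon, length.out = cfg$n_lon)
  nlat <- cfg$n_lat; nlon <- cfg$n_lon
  nsd <- cfg$noise_sd_drivers

  co2 <- cfg$co2_start + cfg$co2_rate * t_rel

  # per-pixel deterministic structure (phases, coefficient heterogeneity)
  rng_substream(cfg$seed, "pixel_structure")
  phase1 <- matrix(stats::runif(nlat * nlon, 0, 2 * pi), nlat, nlon)
  phase2 <- matrix(stats::runif(nlat * nlon, 0, 2 * pi), nlat, nlon)
  phase3 <- matrix(stats::runif(nlat * nlon, 0, 2 * pi), nlat, nlon)
  c_vpd <- matrix(cfg$gpp_vpd_coef *
                    (1 + 0.1 * stats::runif(nlat * nlon, -1, 1)), nlat, nlon)
  c_tmax <- matrix(cfg$gpp_tmax_coef *
                     (1 + 0.1 * stats::runif(nlat * nlon, -1, 1)), nlat, nlon)

  lat_grid <- matrix(lat, nlat, nlon)            # pixel climatology by latitude
  tas0 <- 18 - 0.25 * (lat_grid - 30)
  rh0 <- matrix(70, nlat, nlon)
  b0 <- 1200 - 10 * (lat_grid - 30)

  field <- function() array(NA_real_, c(ny, nlat, nlon))
  noise <- function(name, sd) {
    rng_substream(cfg$seed, name)
    if (sd == 0) array(0, c(ny, nlat, nlon))
    else array(stats::rnorm(ny * nlat * nlon, 0, sd), c(ny, nlat, nlon))
  }
  tas <- tmax <- rh <- precip <- et <- ndep <- pdep <- gpp <- field()

  n_tas <- noise("tas", nsd$tas); n_rh <- noise("rh", nsd$rh)
  n_tmx <- noise("tmax", nsd$tmax); n_pr <- noise("precip", nsd$precip)
  n_et <- noise("et", nsd$et); n_nd <- noise("ndep", nsd$ndep)
  n_pd <- noise("pdep", nsd$pdep)

  hinge <- pmin(years, cfg$ndep_breakyear) - cfg$year_start   # rise then stop
  post <- pmax(years - cfg$ndep_breakyear, 0)                 # decline after

  for (t in seq_len(ny)) {
    iv1 <- sin(2 * pi * t_rel[t] / 7.3 + phase1)  # ENSO-like variability
    iv2 <- sin(2 * pi * t_rel[t] / 3.7 + phase2)
    iv3 <- sin(2 * pi * t_rel[t] / 5.1 + phase3)
    tas[t, , ] <- tas0 + cfg$tas_trend * t_rel[t] + 0.4 * iv1 + n_tas[t, , ]
    rh[t, , ] <- pmin(pmax(rh0 + cfg$rh_trend * t_rel[t] + 1.5 * iv2 +
                             n_rh[t, , ], 5), 100)
    tmax[t, , ] <- tas[t, , ] + 8 + 0.5 * iv3 + n_tmx[t, , ]
    precip[t, , ] <- pmax(60 + cfg$precip_trend * t_rel[t] + 2 * iv2 +
                            n_pr[t, , ], 0)
    et[t, , ] <- pmax(40 + cfg$et_trend * t_rel[t] + 1 * iv1 + n_et[t, , ], 0)
    ndep[t, , ] <- pmax(600 + 8 * hinge[t] - 6 * post[t] + n_nd[t, , ], 0)
    pdep[t, , ] <- pmax(30 + 0.5 * t_rel[t] + n_pd[t, , ], 0)
  }

  vpd_field <- vpd(tas, rh)

  # generating sensitivity trajectory and its trapezoid-accumulated effect
  beta_true_t <- cfg$beta_rel_start + cfg$beta_rel_trend * t_rel
  f_growth <- numeric(ny)
  for (t in 2:ny)
    f_growth[t] <- f_growth[t - 1L] +
      0.5 * (beta_true_t[t - 1L] + beta_true_t[t]) * (co2[t] - co2[t - 1L]) / 1e4

  # GPP responds to VPD / Tmax departures from their year-start state
  vpd_anom <- sweep(vpd_field, c(2L, 3L), vpd_field[1L, , ])
  tmax_anom <- sweep(tmax, c(2L, 3L), tmax[1L, , ])

  growth <- if (cfg$co2_coupling == "exponential") exp(f_growth)
            else 1 + f_growth
  n_gpp <- noise("gpp", 1)   # unit normals, scaled per pixel below
  for (t in seq_len(ny)) {
    det <- b0 * growth[t] +
      c_vpd * vpd_anom[t, , ] + c_tmax * tmax_anom[t, , ]
    gpp[t, , ] <- det + cfg$noise_sd_gpp * b0 * n_gpp[t, , ]
  }

  cube <- function(v, name, units)
    climate_cube(v, years, lat, lon, name, units)
  cubes <- list(
    gpp = cube(gpp, "gpp", "gC m-2 yr-1"),
    tas = cube(tas, "tas", "degC"),
    tmax = cube(tmax, "tmax", "degC"),
    rh = cube(rh, "rh", "%"),
    precip = cube(precip, "precip", "mm month-1"),
    et = cube(et, "et", "mm month-1"),
    ndep = cube(ndep, "ndep", "mg m-2 yr-1"),
    pdep = cube(pdep, "pdep", "mg m-2 yr-1"))

  beta_rel_true <- array(rep(beta_true_t, nlat * nlon), c(ny, nlat, nlon))
  list(cubes = cubes,
       co2 = data.frame(year = years, ppm = co2),
       truth = list(beta_rel_true = beta_rel_true,
                    coef_vpd = c_vpd, coef_tmax = c_tmax,
                    baseline_gpp = b0, config = cfg))
}

#' Trivial monthly disaggregation of an annual cube
#'
#' Replicates each annual value across the 12 months of its year (no
#' phenology). The inverse of [annualize()] with `how = "mean"`.
#'
#' @param cube annual `climate_cube`.
#' @return A monthly `climate_cube`.
#' @export
monthly_disaggregate <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"), is.null(cube$months))
  ny <- length(cube$years)
  idx <- rep(seq_len(ny), each = 12L)
  climate_cube(cube$values[idx, , , drop = FALSE],
               cube$years[idx], cube$lat, cube$lon, cube$varname, cube$units,
               months = rep(1:12, ny))
}

#' Write a scenario to disk
#'
#' One plain-text gridded file per driver variable plus `co2.csv`
#' (columns `year`, `ppm`). Ground truth goes into separate files prefixed
#' `truth_` so a pipeline reading the driver set cannot accidentally consume
#' it: `truth_beta_rel_true.txtgrid` and `truth_coefficients.json`.
#'
#' @param scenario output of [generate_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(scenario$cubes))
    write_cube(scenario$cubes[[nm]], file.path(dir, paste0(nm, ".txtgrid")))
  utils::write.csv(scenario$co2, file.path(dir, "co2.csv"),
                   row.names = FALSE)
  tr <- scenario$truth
  g <- scenario$cubes$gpp
  write_cube(climate_cube(tr$beta_rel_true, g$years, g$lat, g$lon,
                          "beta_rel_true", "% per 100 ppm"),
             file.path(dir, "truth_beta_rel_true.txtgrid"))
  jsonlite::write_json(
    list(coef_vpd = tr$coef_vpd, coef_tmax = tr$coef_tmax,
         baseline_gpp = tr$baseline_gpp,
         config = unclass(tr$config)),
    file.path(dir, "truth_coefficients.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read the driver set of a written scenario
#'
#' Reads only the driver cubes and the CO2 series; `truth_*` files are
#' deliberately excluded (the separation contract between inputs and the
#' recovery oracle).
#'
#' @param dir directory written by [write_scenario()].
#' @return A list `cubes` (named `climate_cube`s) and `co2` (data.frame).
#' @export
read_scenario <- function(dir) {
  files <- list.files(dir, pattern = "\\.txtgrid$", full.names = TRUE)
  files <- files[!grepl("^truth_", basename(files))]
  cubes <- lapply(files, read_cube)
  names(cubes) <- sub("\\.txtgrid$", "", basename(files))
  co2_path <- file.path(dir, "co2.csv")
  if (!file.exists(co2_path))
    stop("co2.csv not found in ", dir, call. = FALSE)
  list(cubes = cubes, co2 = utils::read.csv(co2_path))
}

#' Generate a windowed attribution scenario with known contribution shares
#'
#' Builds, for each pixel, windowed driver anomaly series (independent
#' Gaussian, emulating detrended 15-year window means) and a sensitivity
#' series that is an exact linear combination of them plus noise, with
#' coefficients chosen so the generating standardized-coefficient shares
#' (|coef| times driver standard deviation, normalised) equal `shares`. With
#' orthogonal drivers and no noise the recovered relative contributions equal
#' the generating shares exactly; noise spreads them around the target.
#'
#' @param n_windows number of moving-window positions (default 20, a
#'   34-year record with 15-year windows).
#' @param n_lat,n_lon grid size.
#' @param shares named generating shares, summing to 1 (defaults dominated by
#'   VPD: 0.70 / 0.15 / 0.10 / 0.05 for VPD, Wa, Nit, Pho).
#' @param noise_sd sd of the additive noise on the sensitivity series, in
#'   units of the series' deterministic part (~0.72 sd at default shares).
#' @param seed RNG seed.
#' @return A list: `beta_field` `(window, lat, lon)`, `driver_fields`
#'   (named list of same-shape arrays), `shares` (the generating truth),
#'   `coef_true` (signed generating coefficients).
#' @export
generate_attribution_scenario <- function(n_windows = 20L, n_lat = 10L,
                                          n_lon = 10L,
                                          shares = c(VPD = 0.70, Wa = 0.15,
                                                     Nit = 0.10, Pho = 0.05),
                                          noise_sd = 0.15, seed = 1L) {
  stopifnot(abs(sum(shares) - 1) < 1e-12, all(shares >= 0))
  nm <- names(shares)
  signs <- stats::setNames(rep(1, length(nm)), nm)
  if ("VPD" %in% nm) signs[["VPD"]] <- -1   # rising VPD depresses beta
  if ("Nit" %in% nm) signs[["Nit"]] <- 1
  rng_substream(seed, "attribution")
  dims <- c(n_windows, n_lat, n_lon)
  driver_fields <- lapply(nm, function(x) {
    a <- array(stats::rnorm(prod(dims)), dims)
    # unit sample sd per pixel, so noise-free contributions equal `shares`
    # exactly rather than up to sd sampling error
    for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
      v <- a[, i, j]
      a[, i, j] <- (v - mean(v)) / stats::sd(v)
    }
    a
  })
  names(driver_fields) <- nm
  coef_true <- signs * shares
  beta_field <- array(0, dims)
  for (x in nm) beta_field <- beta_field + coef_true[[x]] * driver_fields[[x]]
  beta_field <- beta_field + array(stats::rnorm(prod(dims), 0, noise_sd), dims)
  list(beta_field = beta_field, driver_fields = driver_fields,
       shares = shares, coef_true = coef_true)
}
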