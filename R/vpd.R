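#' Air pressure from altitude and air temperature
#'
#' Barometric scaling of mean-sea-level pressure with the standard lapse rate
#' (0.0065 K m\eqn{^{-1}}):
#' \deqn{P_a = P_{asl} \left(\frac{T_{as}+273.16}{T_{as}+273.16+0.0065 H}\right)^{5.625}}
#' with \eqn{P_{asl} = 1013.25} hPa. At \eqn{H = 0} the ratio is 1 and
#' \eqn{P_a = P_{asl}}; pressure decreases strictly with altitude.
#'
#' The 273.16 offset is kept as such deliberately (the formulation in use in
#' the VPD literature writes 273.16 here even though Kelvin conversion
#' elsewhere uses 273.15).
#'
#' @param tas air temperature, degrees C. Must exceed -273.15.
#' @param h altitude, metres (non-negative).
#' @param pasl sea-level pressure, hPa.
#' @return Air pressure in hPa, same shape as the inputs.
#' @examples
#' air_pressure(15, 0)     # 1013.25
#' air_pressure(15, 1000)  # < 1013.25
#' @export
air_pressure <- function(tas, h = 0, pasl = 1013.25) {
  if (any(tas <= -273.15, na.rm = TRUE))
    stop("tas must exceed absolute zero (-273.15 C)", call. = FALSE)
  if (any(h < 0, na.rm = TRUE))
    stop("altitude must be non-negative", call. = FALSE)
  tk <- tas + 273.16
  pasl * (tk / (tk + 0.0065 * h))^5.625
}

#' Saturated vapor pressure with a pressure-dependent enhancement factor
#'
#' Magnus-type saturation vapor pressure over water corrected by the moist-air
#' enhancement factor \eqn{f}:
#' \deqn{f = 1 + 7\times 10^{-4} + 3.46\times 10^{-6} P_a}
#' \deqn{SVP = 6.112\, f\, \exp\!\left(\frac{17.67\, T_{as}}{T_{as}+243.5}\right)}
#'
#' @param tas air temperature, degrees C (> -243.5 so the Magnus denominator
#'   stays positive).
#' @param pa air pressure, hPa (see [air_pressure()]); defaults to sea level.
#' @return Saturated vapor pressure, hPa.
#' @examples
#' saturated_vapor_pressure(0)    # ~6.1377 hPa
#' saturated_vapor_pressure(20)   # ~23.47 hPa
#' @export
saturated_vapor_pressure <- function(tas, pa = 1013.25) {
  if (any(tas <= -243.5, na.rm = TRUE))
    stop("tas must exceed -243.5 C", call. = FALSE)
  f <- 1 + 7e-4 + 3.46e-6 * pa
  6.112 * f * exp(17.67 * tas / (tas + 243.5))
}

#' Actual vapor pressure from relative humidity
#'
#' \deqn{AVP = \frac{RH}{100}\, SVP}
#'
#' Relative humidity slightly above 100\% (supersaturation artifacts in
#' reanalysis products) is clipped to 100 with a warning when
#' `clip = TRUE` (the default, up to `clip_max`); RH outside the tolerated
#' range is an error.
#'
#' @param rh relative humidity, percent.
#' @param svp saturated vapor pressure, hPa.
#' @param clip clip RH in (100, `clip_max`] down to 100?
#' @param clip_max largest RH treated as a clippable artifact.
#' @return Actual vapor pressure, hPa.
#' @export
actual_vapor_pressure <- function(rh, svp, clip = TRUE, clip_max = 105) {
  bad_low <- any(rh < 0, na.rm = TRUE)
  hi <- suppressWarnings(max(rh, na.rm = TRUE))
  if (!is.finite(hi)) hi <- 0
  if (bad_low || (!clip && hi > 100) || hi > clip_max)
    stop("relative humidity outside [0, 100]", call. = FALSE)
  if (clip && hi > 100) {
    n <- sum(rh > 100, na.rm = TRUE)
    warning(sprintf("clipped %d supersaturated RH value(s) to 100", n),
            call. = FALSE)
    rh <- pmin(rh, 100)
  }
  (rh / 100) * svp
}

#' Vapor pressure deficit
#'
#' VPD is the difference between saturated and actual vapor pressure,
#' \eqn{VPD = SVP - AVP}, in hPa. Two ingestion dialects are supported:
#' `vpd()` takes relative humidity (the CFSR / MERRA / ERA-Interim / JRA-55
#' style inputs), `vpd_from_avp()` takes actual vapor pressure directly (the
#' HadCRUT4 style input). On consistent inputs
#' (\eqn{AVP = RH/100 \cdot SVP}) the two paths agree exactly.
#'
#' By default altitude is 0 so the enhancement factor is evaluated at
#' sea-level pressure; pass an elevation field to apply the barometric
#' correction.
#'
#' @param tas air temperature, degrees C.
#' @param rh relative humidity, percent.
#' @param avp actual vapor pressure, hPa.
#' @param h altitude, metres.
#' @param ... passed to [actual_vapor_pressure()] (clipping control).
#' @return VPD in hPa (non-negative whenever RH <= 100).
#' @examples
#' vpd(20, rh = 50)          # ~11.73 hPa
#' vpd(20, rh = 100)         # 0
#' vpd_from_avp(20, avp = 10)
#' @export
vpd <- function(tas, rh, h = 0, ...) {
  svp <- saturated_vapor_pressure(tas, air_pressure(tas, h))
  svp - actual_vapor_pressure(rh, svp, ...)
}

#' @rdname vpd
#' @export
vpd_from_avp <- function(tas, avp, h = 0) {
  if (any(avp < 0, na.rm = TRUE))
    stop("actual vapor pressure must be non-negative", call. = FALSE)
  saturated_vapor_pressure(tas, air_pressure(tas, h)) - avp
}

#' CO2 assimilation rate under a vapor pressure gradient
#'
#' The stomatal-limitation identity linking transpiration `trans`, ambient and
#' inner-leaf CO2 partial pressures and VPD:
#' \deqn{A = \frac{T\, C_a}{1.6\, VPD}\left(1 - \frac{C_i}{C_a}\right)}
#' Holding transpiration and the partial pressures fixed, assimilation is
#' inversely proportional to VPD — doubling VPD halves A. This is the
#' mechanism by which a rising VPD depresses the CO2 response of GPP.
#'
#' @param trans transpiration rate.
#' @param ca ambient CO2 partial pressure (> 0).
#' @param ci inner-leaf CO2 partial pressure.
#' @param vpd_hpa vapor pressure deficit (> 0), hPa.
#' @return Assimilation rate (units of `trans * ca / vpd_hpa`).
#' @examples
#' assimilation_rate(1, 400, 280, 10)  # 7.5
#' @export
assimilation_rate <- function(trans, ca, ci, vpd_hpa) {
  if (any(vpd_hpa <= 0, na.rm = TRUE))
    stop("VPD must be positive", call. = FALSE)
  if (any(ca <= 0, na.rm = TRUE))
    stop("ambient CO2 partial pressure must be positive", call. = FALSE)
  (trans * ca) / (1.6 * vpd_hpa) * (1 - ci / ca)
}

#' Derive a VPD cube from temperature and humidity cubes
#'
#' Elementwise application of [vpd()] / [vpd_from_avp()] to co-registered
#' cubes. Supply either `rh` (relative humidity, percent) or `avp` (actual
#' vapor pressure, hPa). Masks are intersected.
#'
#' @param tas `climate_cube` of air temperature (degrees C).
#' @param rh,avp one of: `climate_cube` of relative humidity (`%`) or of
#'   actual vapor pressure (hPa).
#' @param elev optional elevation matrix `(lat, lon)` in metres; default 0.
#' @return A `climate_cube` named `"vpd"` with units `"hPa"`.
#' @export
vpd_cube <- function(tas, rh = NULL, avp = NULL, elev = NULL) {
  stopifnot(inherits(tas, "climate_cube"))
  hum <- if (!is.null(rh)) rh else avp
  if (is.null(hum)) stop("supply either `rh` or `avp`", call. = FALSE)
  if (!same_grid(tas, hum) || !identical(tas$years, hum$years))
    stop("temperature and humidity cubes are not co-registered", call. = FALSE)
  h <- if (is.null(elev)) 0 else
    aperm(array(elev, c(length(tas$lat), length(tas$lon), dim(tas$values)[1L])),
          c(3L, 1L, 2L))
  vals <- if (!is.null(rh)) vpd(tas$values, rh$values, h = h)
          else vpd_from_avp(tas$values, avp$values, h = h)
  climate_cube(vals, tas$years, tas$lat, tas$lon, "vpd", "hPa",
               months = tas$months, mask = tas$mask & hum$mask)
}
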