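#' Per-pixel linear trend field
#'
#' Container for per-pixel trend results: slope, two-sided p-value and a
#' significance flag at the chosen level, on the same lat-lon grid as the
#' source cube. Built by [pixel_trend_map()] and consumed by
#' [fraction_with_trend()].
#'
#' @param slope,p_value numeric matrices `(lat, lon)`.
#' @param significant logical matrix, `p_value < alpha`.
#' @param lat,lon coordinate vectors.
#' @param alpha the significance level the flag was computed at.
#' @param n_time number of time points entering each fit.
#' @return An object of class `trend_field`.
#' @export
trend_field <- function(slope, p_value, significant, lat, lon,
                        alpha = 0.05, n_time = NA_integer_) {
  stopifnot(identical(dim(slope), dim(p_value)),
            identical(dim(slope), dim(significant)))
  structure(list(slope = slope, p_value = p_value, significant = significant,
                 lat = lat, lon = lon, alpha = alpha, n_time = n_time),
            class = "trend_field")
}

#' @export
print.trend_field <- function(x, ...) {
  ok <- is.finite(x$slope)
  cat(sprintf("<trend_field> %d x %d grid, %d valid pixels\n",
              length(x$lat), length(x$lon), sum(ok)))
  if (any(ok))
    cat(sprintf("  slope range [%.4g, %.4g]; %d significant at p < %g\n",
                min(x$slope[ok]), max(x$slope[ok]),
                sum(x$significant[ok]), x$alpha))
  invisible(x)
}

#' Fit a linear trend in every pixel of a cube
#'
#' Applies the same slope engine as [beta_trend()] to each pixel's time
#' series: OLS slope against the time axis (years, or any numeric axis such
#' as window centres) with a two-sided t-test on n-2 degrees of freedom.
#' Pixels with fewer than 3 valid time points are masked. No autocorrelation
#' correction is applied.
#'
#' @param cube a `climate_cube` (annual), or a plain 3-d array with `time_axis`
#'   supplied.
#' @param time_axis numeric axis for the regression x (default: the cube's
#'   years).
#' @param alpha significance level for the flag.
#' @return A [trend_field()].
#' @export
pixel_trend_map <- function(cube, time_axis = NULL, alpha = 0.05) {
  if (inherits(cube, "climate_cube")) {
    vals <- cube$values
    if (is.null(time_axis)) time_axis <- cube$years
    lat <- cube$lat; lon <- cube$lon
  } else {
    vals <- cube
    if (is.null(time_axis))
      stop("time_axis required for a bare array", call. = FALSE)
    lat <- seq_len(dim(vals)[2L]); lon <- seq_len(dim(vals)[3L])
  }
  d <- dim(vals)
  slope <- p_val <- matrix(NA_real_, d[2L], d[3L])
  for (i in seq_len(d[2L])) for (j in seq_len(d[3L])) {
    y <- vals[, i, j]
    ok <- is.finite(y)
    if (sum(ok) < 3L) next
    tr <- slope_test(time_axis[ok], y[ok], alpha = alpha)
    slope[i, j] <- tr$slope
    p_val[i, j] <- tr$p_value
  }
  trend_field(slope, p_val, is.finite(p_val) & p_val < alpha, lat, lon,
              alpha = alpha, n_time = d[1L])
}

#' Nearest-neighbour regridding onto a target grid
#'
#' Each target cell takes the value of the nearest source cell centre in the
#' plain lat/lon Euclidean metric (degrees); ties break toward the lower
#' source index. Masked source cells propagate to every target cell that maps
#' to them. Identical grids reproduce the input (regridding is idempotent on
#' matching grids).
#'
#' @param cube source `climate_cube`.
#' @param target_lat,target_lon target cell-centre coordinate vectors.
#' @return A `climate_cube` on the target grid.
#' @export
regrid_nearest <- function(cube, target_lat, target_lon) {
  stopifnot(inherits(cube, "climate_cube"))
  target_lon <- normalize_lon(target_lon)
  if (min(target_lat) > max(cube$lat) || max(target_lat) < min(cube$lat) ||
      min(target_lon) > max(cube$lon) || max(target_lon) < min(cube$lon))
    stop("source and target grids do not overlap", call. = FALSE)
  nearest <- function(targets, centers) {
    vapply(targets, function(t) which.min(abs(centers - t)), integer(1L))
  }
  ilat <- nearest(target_lat, cube$lat)
  ilon <- nearest(target_lon, cube$lon)
  vals <- cube$values[, ilat, ilon, drop = FALSE]
  climate_cube(vals, cube$years, target_lat, target_lon,
               cube$varname, cube$units, months = cube$months)
}

#' Area weights proportional to the cosine of latitude
#' @param lat latitude vector (degrees).
#' @param nlon number of longitude cells (weights are replicated along lon).
#' @return A `(lat, lon)` matrix of unnormalised weights.
#' @export
cos_lat_weights <- function(lat, nlon) {
  matrix(cos(lat * pi / 180), length(lat), nlon)
}

#' Area-weighted spatial mean
#'
#' Mean of a `(lat, lon)` field, or of each time slice of a cube, with
#' weights proportional to cos(latitude of the cell centre), normalised over
#' the unmasked cells of the requested region.
#'
#' @param x a `climate_cube` or a `(lat, lon)` matrix.
#' @param lat latitude vector (required for a bare matrix).
#' @param region optional logical `(lat, lon)` matrix; `TRUE` = include.
#' @param weighted set `FALSE` for a plain cell-count mean (comparison mode).
#' @return For a cube: numeric vector, one value per time step. For a
#'   matrix: a scalar.
#' @export
area_weighted_mean <- function(x, lat = NULL, region = NULL, weighted = TRUE) {
  if (inherits(x, "climate_cube")) {
    nt <- dim(x$values)[1L]
    return(vapply(seq_len(nt), function(t)
      area_weighted_mean(matrix(x$values[t, , ],
                                length(x$lat), length(x$lon)),
                         lat = x$lat, region = region, weighted = weighted),
      numeric(1L)))
  }
  stopifnot(is.matrix(x), !is.null(lat))
  w <- if (weighted) cos_lat_weights(lat, ncol(x)) else
    matrix(1, nrow(x), ncol(x))
  keep <- is.finite(x)
  if (!is.null(region)) keep <- keep & region
  if (!any(keep)) stop("empty region: no unmasked cells", call. = FALSE)
  sum(x[keep] * w[keep]) / sum(w[keep])
}

#' Area fraction with a trend of a given sign
#'
#' Area-weighted fraction of valid pixels whose fitted slope has the
#' requested sign, optionally restricted to significant trends (p below the
#' field's level). The denominator is all valid (unmasked) pixels in the
#' region, so the negative, positive and zero fractions add to 1.
#'
#' @param trend a [trend_field()].
#' @param sign one of `"negative"`, `"positive"`, `"zero"`.
#' @param significant_only count only pixels with `significant == TRUE`?
#' @param region optional logical `(lat, lon)` inclusion matrix.
#' @param weighted cos-latitude area weighting (default) or cell counting.
#' @return A scalar fraction in \[0, 1\].
#' @export
fraction_with_trend <- function(trend, sign = c("negative", "positive", "zero"),
                                significant_only = FALSE, region = NULL,
                                weighted = TRUE) {
  stopifnot(inherits(trend, "trend_field"))
  sign <- match.arg(sign)
  valid <- is.finite(trend$slope)
  if (!is.null(region)) valid <- valid & region
  if (!any(valid)) stop("empty trend field", call. = FALSE)
  sel <- switch(sign,
                negative = trend$slope < 0,
                positive = trend$slope > 0,
                zero     = trend$slope == 0)
  sel <- sel & valid
  if (significant_only) sel <- sel & trend$significant
  w <- if (weighted) cos_lat_weights(trend$lat, length(trend$lon)) else
    matrix(1, length(trend$lat), length(trend$lon))
  sum(w[sel]) / sum(w[valid])
}

#' Region mask for latitudes at or above a threshold
#'
#' Default region of interest: northern middle and high latitudes, i.e. all
#' (land) cells with centre latitude >= 30 degrees N. The bound is
#' configurable since definitions differ between studies.
#'
#' @param lat,lon grid coordinate vectors.
#' @param lat_min inclusive latitude threshold (degrees N), default 30.
#' @return Logical `(lat, lon)` matrix.
#' @export
northern_mask <- function(lat, lon, lat_min = 30) {
  matrix(lat >= lat_min, length(lat), length(lon))
}
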