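#' Parameters for the stochastic daily weather generator
#'
#' Bundles the knobs of a simple monsoonal weather model: a sinusoidal annual
#' cycle for temperature and clear-sky solar radiation, two-state (wet/dry)
#' first-order Markov rainfall occurrence (wet-spell persistence, as in
#' Richardson-type generators) with gamma-distributed wet-day depths, and
#' multiplicative radiation attenuation on wet days. Monsoon onset, length,
#' and overall wetness vary from year to year, which is what makes rainfed
#' yields vary between years.
#'
#' @param mean_temp Mean annual air temperature, degC.
#' @param seasonal_amp Amplitude of the annual temperature cycle, degC.
#' @param diurnal_range Mean daily tmax - tmin, degC.
#' @param monsoon_onset Mean monsoon onset, day of year.
#' @param monsoon_length Mean monsoon duration, days.
#' @param onset_sd,length_sd Interannual standard deviations of onset and
#'   length, days.
#' @param wetness_sd Interannual standard deviation of the multiplicative
#'   monsoon wetness factor applied to the in-monsoon wet-day probability
#'   (good vs bad monsoon years).
#' @param p_wet_monsoon,p_wet_dry Marginal wet-day probability inside /
#'   outside the monsoon, in \[0, 1\].
#' @param wet_persistence P(wet | yesterday wet); the dry-to-wet transition
#'   probability is derived so the marginal wet-day probability is preserved.
#' @param wet_depth_mean Mean wet-day rainfall depth, mm (gamma distributed).
#' @param gamma_shape Shape of the gamma depth distribution (dimensionless).
#' @param srad_clear Annual-mean clear-sky solar radiation, MJ m-2 d-1.
#' @param srad_amp Amplitude of the annual clear-sky radiation cycle,
#'   MJ m-2 d-1.
#' @param rain_atten Multiplicative radiation attenuation on wet days, (0, 1\].
#' @param temp_noise_sd Daily temperature noise sd, degC.
#' @param srad_noise_sd Daily radiation noise sd, MJ m-2 d-1.
#'
#' @return An object of class `weather_params` (a validated list).
#' @seealso [gen_weather()]
#' @export
weather_params <- function(mean_temp = 26, seasonal_amp = 3, diurnal_range = 9,
                           monsoon_onset = 150, monsoon_length = 110,
                           onset_sd = 12, length_sd = 15, wetness_sd = 0.25,
                           p_wet_monsoon = 0.55, p_wet_dry = 0.05,
                           wet_persistence = 0.78,
                           wet_depth_mean = 11, gamma_shape = 0.75,
                           srad_clear = 18, srad_amp = 4, rain_atten = 0.78,
                           temp_noise_sd = 1, srad_noise_sd = 1.5) {
  p <- list(mean_temp = mean_temp, seasonal_amp = seasonal_amp,
            diurnal_range = diurnal_range, monsoon_onset = monsoon_onset,
            monsoon_length = monsoon_length, onset_sd = onset_sd,
            length_sd = length_sd, wetness_sd = wetness_sd,
            p_wet_monsoon = p_wet_monsoon,
            p_wet_dry = p_wet_dry, wet_persistence = wet_persistence,
            wet_depth_mean = wet_depth_mean,
            gamma_shape = gamma_shape, srad_clear = srad_clear,
            srad_amp = srad_amp, rain_atten = rain_atten,
            temp_noise_sd = temp_noise_sd, srad_noise_sd = srad_noise_sd)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                     is.finite(x), logical(1)))
  if (p_wet_monsoon < 0 || p_wet_monsoon > 1 || p_wet_dry < 0 || p_wet_dry > 1)
    stop("wet-day probabilities must lie in [0, 1]", call. = FALSE)
  if (wet_persistence < 0 || wet_persistence > 1)
    stop("wet_persistence must lie in [0, 1]", call. = FALSE)
  if (wet_depth_mean <= 0)
    stop("gamma wet-day depth mean must be > 0", call. = FALSE)
  if (gamma_shape <= 0) stop("gamma shape must be > 0", call. = FALSE)
  if (seasonal_amp < 0 || srad_amp < 0 || diurnal_range < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (rain_atten <= 0 || rain_atten > 1)
    stop("rain_atten must lie in (0, 1]", call. = FALSE)
  structure(p, class = "weather_params")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a multi-year daily weather series
#'
#' Produces a contiguous daily series (leap days included) of solar radiation,
#' maximum/minimum air temperature, and precipitation. The generator is a pure
#' function of `(params, years, seed, start_year)`: the same arguments always
#' give the same series.
#'
#' @param params A [weather_params()] object.
#' @param years Number of calendar years to generate (>= 1).
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @param start_year First calendar year of the series.
#'
#' @return A data frame with columns `date` (Date), `srad` (MJ m-2 d-1),
#'   `tmax`, `tmin` (degC), and `precip` (mm d-1), one row per day, satisfying
#'   `tmax >= tmin`, `srad >= 0`, `precip >= 0`.
#' @examples
#' w <- gen_weather(weather_params(), years = 2, seed = 1)
#' head(w)
#' @export
gen_weather <- function(params = weather_params(), years, seed = 1L,
                        start_year = 2000L) {
  if (!inherits(params, "weather_params")) params <- do.call(weather_params, params)
  if (!is.numeric(years) || length(years) != 1L || years < 1)
    stop("years must be a count >= 1", call. = FALSE)
  years <- as.integer(years)
  with_seed(seed, {
    out <- vector("list", years)
    for (i in seq_len(years)) {
      yr <- start_year + i - 1L
      dates <- seq(as.Date(sprintf("%d-01-01", yr)),
                   as.Date(sprintf("%d-12-31", yr)), by = "day")
      n <- length(dates)
      doy <- as.POSIXlt(dates)$yday + 1L
      # annual cycle peaking mid-monsoon (~doy 201 for default onset)
      seas <- sin(2 * pi * (doy - 110) / 365.25)
      tmean <- params$mean_temp + params$seasonal_amp * seas +
        stats::rnorm(n, 0, params$temp_noise_sd)
      half <- pmax(0.25, params$diurnal_range / 2 +
                     stats::rnorm(n, 0, params$temp_noise_sd / 2))
      onset <- params$monsoon_onset + stats::rnorm(1, 0, params$onset_sd)
      len <- max(0, params$monsoon_length + stats::rnorm(1, 0, params$length_sd))
      in_monsoon <- doy >= onset & doy < onset + len
      wetness <- max(0.2, stats::rnorm(1, 1, params$wetness_sd))
      p_wet <- ifelse(in_monsoon,
                      min(0.95, params$p_wet_monsoon * wetness),
                      params$p_wet_dry)
      # first-order Markov occurrence preserving the marginal probability p:
      # P(wet|wet) = wet_persistence, P(wet|dry) = p (1 - p_ww) / (1 - p)
      p_ww <- pmin(1, pmax(p_wet, params$wet_persistence))
      p_dw <- pmin(1, p_wet * (1 - p_ww) / pmax(1e-9, 1 - p_wet))
      u <- stats::runif(n)
      wet <- logical(n)
      wet[1] <- u[1] < p_wet[1]
      for (d in 2:n)
        wet[d] <- u[d] < if (wet[d - 1]) p_ww[d] else p_dw[d]
      depth <- stats::rgamma(n, shape = params$gamma_shape,
                             rate = params$gamma_shape / params$wet_depth_mean)
      srad <- pmax(0, (params$srad_clear + params$srad_amp * seas) *
                     ifelse(wet, params$rain_atten, 1) +
                     stats::rnorm(n, 0, params$srad_noise_sd))
      out[[i]] <- data.frame(date = dates, srad = srad,
                             tmax = tmean + half, tmin = tmean - half,
                             precip = ifelse(wet, depth, 0))
    }
    do.call(rbind, out)
  })
}

#' Quality-control gap filling of a daily weather series
#'
#' Fills missing values in the numeric weather columns by linear interpolation
#' between the flanking observed values (the standard weather-station QC step).
#' Gaps at the series boundary cannot be interpolated two-sided and are filled
#' with the nearest observed value, with a warning. Observed values are never
#' changed, so the operation is idempotent.
#'
#' @param weather Data frame with columns `date, srad, tmax, tmin, precip`;
#'   missing values coded `NA`.
#' @return The weather data frame with every gap filled.
#' @examples
#' w <- gen_weather(weather_params(), years = 1, seed = 1)
#' w$tmax[10:12] <- NA
#' filled <- qc_fill(w)
#' @export
qc_fill <- function(weather) {
  stopifnot(is.data.frame(weather))
  cols <- intersect(c("srad", "tmax", "tmin", "precip"), names(weather))
  n <- nrow(weather)
  filled_any_boundary <- FALSE
  for (col in cols) {
    v <- weather[[col]]
    if (!anyNA(v)) next
    obs <- which(!is.na(v))
    if (length(obs) == 0L)
      stop(sprintf("column '%s' has no observed values to interpolate from", col),
           call. = FALSE)
    if (is.na(v[1L]) || is.na(v[n])) filled_any_boundary <- TRUE
    weather[[col]] <- stats::approx(obs, v[obs], xout = seq_len(n),
                                    method = "linear", rule = 2)$y
  }
  if (filled_any_boundary)
    warning("gap at series boundary filled with nearest observed value",
            call. = FALSE)
  # interpolating tmax and tmin independently can cross on filled rows only
  bad <- weather$tmax < weather$tmin
  if (any(bad)) {
    mid <- (weather$tmax[bad] + weather$tmin[bad]) / 2
    weather$tmax[bad] <- mid
    weather$tmin[bad] <- mid
  }
  weather
}

#' Read / write a weather CSV (`date,srad,tmax,tmin,precip`, ISO dates)
#'
#' @param weather Weather data frame (see [gen_weather()]).
#' @param path File path.
#' @return `read_weather_csv()` returns the weather data frame;
#'   `write_weather_csv()` returns `path` invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  stopifnot(all(c("date", "srad", "tmax", "tmin", "precip") %in% names(weather)))
  out <- weather[, c("date", "srad", "tmax", "tmin", "precip")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "srad", "tmax", "tmin", "precip")
  if (!all(need %in% names(w)))
    stop(sprintf("weather CSV '%s' must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  w$date <- as.Date(w$date)
  w
}
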