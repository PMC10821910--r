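#' Crop calendar for one rice cycle
#'
#' Calendar dates are expressed as days of year so that the same calendar can
#' be applied to every year of a weather series. The 50% flowering date is
#' fixed at 30 days before maturity when not supplied, following standard
#' practice for calibrating rice phenology from farmer-reported maturity.
#'
#' @param establishment `"transplanted"` or `"direct-seeded"`.
#' @param sowing_doy Sowing day of year.
#' @param transplanting_doy Transplanting day of year (transplanted rice only).
#' @param maturity_doy Physiological maturity day of year.
#' @param flowering_doy 50% flowering day of year; default `maturity_doy - 30`.
#' @return An object of class `crop_calendar`.
#' @export
crop_calendar <- function(establishment = c("transplanted", "direct-seeded"),
                          sowing_doy, transplanting_doy = NULL, maturity_doy,
                          flowering_doy = maturity_doy - 30L) {
  establishment <- match.arg(establishment)
  if (establishment == "direct-seeded") transplanting_doy <- sowing_doy
  if (is.null(transplanting_doy))
    stop("transplanted rice needs a transplanting_doy", call. = FALSE)
  stopifnot(sowing_doy >= 1, maturity_doy <= 366)
  if (!(sowing_doy <= transplanting_doy && transplanting_doy < flowering_doy &&
        flowering_doy < maturity_doy))
    stop("calendar must satisfy sowing <= transplanting < flowering < maturity",
         call. = FALSE)
  structure(list(establishment = establishment,
                 sowing_doy = as.integer(sowing_doy),
                 transplanting_doy = as.integer(transplanting_doy),
                 flowering_doy = as.integer(flowering_doy),
                 maturity_doy = as.integer(maturity_doy)),
            class = "crop_calendar")
}

#' Phenological development-rate parameters
#'
#' Development rates per unit thermal time for the four ORYZA-convention
#' stages: juvenile (DVS 0-0.4), photoperiod-sensitive (0.4-0.65), panicle
#' development (0.65-1.0), and reproductive (1.0-2.0). The development stage
#' DVS runs from 0 at emergence to 1 at flowering and 2 at maturity.
#' Photoperiod sensitivity is off by default (the optimum photoperiod of 10 h
#' is then never binding and DVRI acts as a plain thermal rate).
#'
#' Default rates are generic indica values; [calibrate_development_rates()]
#' rescales them to match a local crop calendar.
#'
#' @param dvrj,dvri,dvrp,dvrr Development rates, (degC d)^-1; all > 0.
#' @param t_base,t_opt,t_max Cardinal temperatures of the piecewise-linear
#'   thermal-time response, degC (base 14, optimum 30, maximum 42).
#' @param photoperiod_opt Maximum optimum photoperiod, h.
#' @param photoperiod_sens Logical; photoperiod sensitivity (off by default).
#' @return An object of class `phenology_params`.
#' @export
phenology_params <- function(dvrj = 0.000773, dvri = 0.000758,
                             dvrp = 0.000784, dvrr = 0.001784,
                             t_base = 14, t_opt = 30, t_max = 42,
                             photoperiod_opt = 10, photoperiod_sens = FALSE) {
  if (any(c(dvrj, dvri, dvrp, dvrr) <= 0))
    stop("development rates must be > 0", call. = FALSE)
  stopifnot(t_base < t_opt, t_opt < t_max)
  structure(list(dvrj = dvrj, dvri = dvri, dvrp = dvrp, dvrr = dvrr,
                 t_base = t_base, t_opt = t_opt, t_max = t_max,
                 photoperiod_opt = photoperiod_opt,
                 photoperiod_sens = isTRUE(photoperiod_sens)),
            class = "phenology_params")
}

#' Daily effective temperature (thermal-time increment)
#'
#' Piecewise-linear response of development to daily mean temperature: zero at
#' or below the 14 degC base, rising linearly to `t_opt - t_base` degC d at the
#' 30 degC optimum, then declining linearly to zero at the 42 degC maximum.
#'
#' @param tmin,tmax Daily minimum and maximum air temperature, degC
#'   (`tmax >= tmin`); vectorised.
#' @param t_base,t_opt,t_max Cardinal temperatures, degC.
#' @return Thermal-time increment, degC d.
#' @examples
#' effective_temperature(19, 29)  # mean 24 degC -> 10 degC d
#' @export
effective_temperature <- function(tmin, tmax, t_base = 14, t_opt = 30,
                                  t_max = 42) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin", call. = FALSE)
  tm <- (tmin + tmax) / 2
  up <- pmin(pmax(tm - t_base, 0), t_opt - t_base)
  down <- ifelse(tm > t_opt,
                 (t_opt - t_base) * pmax(t_max - tm, 0) / (t_max - t_opt) -
                   (t_opt - t_base),
                 0)
  up + down
}

# Cumulative thermal-time thresholds of the DVS knots 0, 0.4, 0.65, 1, 2.
tt_knots <- function(phen) {
  cumsum(c(0.4 / phen$dvrj, 0.25 / phen$dvri, 0.35 / phen$dvrp, 1 / phen$dvrr))
}

# Map cumulative thermal time to DVS via the piecewise-linear stage structure.
dvs_from_tt <- function(ctt, phen) {
  kn <- tt_knots(phen)
  stats::approx(c(0, kn), c(0, 0.4, 0.65, 1, 2),
                xout = pmin(ctt, kn[4]), rule = 2)$y
}

#' Simulate phenology over a weather series
#'
#' Integrates the development stage DVS daily as stage rate x effective
#' temperature from the start date and returns the first dates at which DVS
#' reaches 1 (flowering) and 2 (maturity). With constant rates per stage this
#' reduces to thresholds on cumulative thermal time.
#'
#' @param weather Daily weather data frame covering the full cycle.
#' @param start_date Date development starts (sowing).
#' @param params A [phenology_params()] object.
#' @return A list with `flowering` and `maturity` (Dates), `days_to_flowering`,
#'   `days_to_maturity` (counts from `start_date`, day 1 = start), and `dvs`
#'   (daily DVS from start to maturity).
#' @export
simulate_phenology <- function(weather, start_date, params = phenology_params()) {
  start_date <- as.Date(start_date)
  i0 <- match(start_date, as.Date(weather$date))
  if (is.na(i0)) stop("start_date not covered by weather", call. = FALSE)
  w <- weather[i0:nrow(weather), ]
  teff <- effective_temperature(w$tmin, w$tmax, params$t_base, params$t_opt,
                                params$t_max)
  ctt <- cumsum(teff)
  kn <- tt_knots(params)
  fl <- match(TRUE, ctt >= kn[3])
  mat <- match(TRUE, ctt >= kn[4])
  if (is.na(fl) || is.na(mat))
    stop("cycle incomplete: weather series exhausted before maturity",
         call. = FALSE)
  list(flowering = w$date[fl], maturity = w$date[mat],
       days_to_flowering = fl, days_to_maturity = mat,
       dvs = dvs_from_tt(ctt[seq_len(mat)], params))
}

# Mean simulated days (across sowing dates) to reach a cumulative
# thermal-time threshold. `ctt` is the cumulative thermal time over the whole
# series and `starts` the per-year sowing indices; a year contributes Inf if
# the threshold is never reached within the remaining series (the bisection
# then pushes toward faster rates).
mean_days_to_tt <- function(ctt, starts, tt_target) {
  n <- length(ctt)
  days <- vapply(starts, function(i0) {
    base <- if (i0 > 1L) ctt[i0 - 1L] else 0
    j <- findInterval(base + tt_target, ctt, left.open = TRUE) + 1L
    if (j > n) Inf else as.numeric(j - i0 + 1L)
  }, numeric(1))
  mean(days)
}

#' Calibrate development rates against a crop calendar
#'
#' DRATE-style calibration: bisection on a single scalar multiplier applied to
#' the three pre-flowering rates (DVRJ, DVRI, DVRP) so that the mean simulated
#' flowering date across the weather years matches the calendar within one
#' day, then bisection on DVRR so the mean maturity date matches. DVRI is
#' inert (no photoperiod sensitivity). If only maturity is known the calendar
#' convention flowering = maturity - 30 d applies (see [crop_calendar()]).
#'
#' @param weather Multi-year daily weather data frame.
#' @param calendar A [crop_calendar()].
#' @param base Starting [phenology_params()]; the calibrated parameters keep
#'   its relative pre-flowering rate structure.
#' @param tol_days Matching tolerance on the mean date, days.
#' @return Calibrated [phenology_params()].
#' @export
calibrate_development_rates <- function(weather, calendar,
                                        base = phenology_params(),
                                        tol_days = 1) {
  stopifnot(inherits(calendar, "crop_calendar"))
  target_fl <- calendar$flowering_doy - calendar$sowing_doy + 1L
  target_mat <- calendar$maturity_doy - calendar$sowing_doy + 1L
  tt_pre1 <- sum(c(0.4 / base$dvrj, 0.25 / base$dvri, 0.35 / base$dvrp))

  # cumulative thermal time over the whole series, and per-year sowing indices
  dates <- as.Date(weather$date)
  ctt <- cumsum(effective_temperature(weather$tmin, weather$tmax,
                                      base$t_base, base$t_opt, base$t_max))
  yrs <- unique(as.POSIXlt(dates)$year + 1900L)
  starts <- stats::na.omit(match(as.Date(sprintf("%d-01-01", yrs)) +
                                   (calendar$sowing_doy - 1L), dates))
  # only sowing dates whose full cycle (plus slack) can be observed
  starts <- starts[length(dates) - starts + 1L >= target_mat + 30L]
  if (length(starts) == 0L)
    stop("calendar dates fall outside weather coverage", call. = FALSE)

  bisect <- function(f, lo, hi, n = 60L) {
    # f is non-increasing in its argument (larger rate -> earlier date)
    flo <- f(lo); fhi <- f(hi)
    if (flo < -tol_days || fhi > tol_days)
      stop("calibration infeasible: target duration outside achievable range",
           call. = FALSE)
    for (i in seq_len(n)) {
      mid <- sqrt(lo * hi)
      fm <- f(mid)
      if (abs(fm) <= 0.5) return(mid)
      if (fm > 0) lo <- mid else hi <- mid
    }
    mid
  }

  # pre-flowering multiplier: simulated mean flowering day - target
  obj_pre <- function(m)
    mean_days_to_tt(ctt, starts, tt_pre1 / m) - target_fl
  m <- bisect(obj_pre, 1e-2, 1e2)
  cal <- phenology_params(dvrj = base$dvrj * m, dvri = base$dvri * m,
                          dvrp = base$dvrp * m, dvrr = base$dvrr,
                          t_base = base$t_base, t_opt = base$t_opt,
                          t_max = base$t_max,
                          photoperiod_opt = base$photoperiod_opt,
                          photoperiod_sens = base$photoperiod_sens)
  tt_pre <- tt_pre1 / m
  obj_rr <- function(r)
    mean_days_to_tt(ctt, starts, tt_pre + 1 / r) - target_mat
  r <- bisect(obj_rr, 1e-5, 1)
  cal$dvrr <- r
  fl_err <- obj_pre(m)
  mat_err <- obj_rr(r)
  if (abs(fl_err) > tol_days || abs(mat_err) > tol_days)
    stop("calibration infeasible: could not match calendar within tolerance",
         call. = FALSE)
  cal
}
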