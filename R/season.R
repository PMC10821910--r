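#' Temperature-stress parameters
#'
#' The crop dies (yield zero) after `lethal_run` consecutive days with mean
#' air temperature below `t_lethal`; spikelet sterility rises linearly with
#' daily maximum temperature above `t_sterility` during the flowering window.
#'
#' @param t_lethal Lethal low-temperature threshold on daily mean, degC (12).
#' @param lethal_run Consecutive cold days that kill the crop (3).
#' @param t_sterility Critical temperature for spikelet sterility, degC (35.6).
#' @param sterility_slope Sterile fraction per degC above the threshold (0.10).
#' @param dvs_window DVS interval defining the flowering window (0.96-1.2).
#' @param par_fraction Photosynthetically active fraction of solar energy (0.5).
#' @param stem_reserve_fraction Fraction of stem carbohydrates stored as
#'   reserves and remobilised to grain (0.2).
#' @return An object of class `stress_params`.
#' @export
stress_params <- function(t_lethal = 12, lethal_run = 3, t_sterility = 35.6,
                          sterility_slope = 0.10, dvs_window = c(0.96, 1.2),
                          par_fraction = 0.5, stem_reserve_fraction = 0.2) {
  stopifnot(lethal_run >= 1, sterility_slope >= 0,
            length(dvs_window) == 2L, dvs_window[1] < dvs_window[2],
            par_fraction > 0, par_fraction <= 1,
            stem_reserve_fraction >= 0, stem_reserve_fraction <= 1)
  structure(list(t_lethal = t_lethal, lethal_run = as.integer(lethal_run),
                 t_sterility = t_sterility, sterility_slope = sterility_slope,
                 dvs_window = dvs_window, par_fraction = par_fraction,
                 stem_reserve_fraction = stem_reserve_fraction),
            class = "stress_params")
}

#' Canopy and partitioning parameters of the season simulator
#'
#' The simulator accumulates biomass daily as radiation-use efficiency x
#' intercepted photosynthetically active radiation x transpiration ratio, with
#' light interception from a prescribed leaf-area curve rising linearly to its
#' maximum at flowering (DVS 1) and declining toward maturity. Grain yield is
#' harvest index x final biomass, reduced by spikelet sterility, plus
#' remobilised stem reserves; a harvest-index ceiling bounds the sum.
#'
#' @param rue Radiation-use efficiency, g dry matter per MJ PAR (2.2).
#' @param k_ext Canopy light-extinction coefficient (0.5).
#' @param lai_max Peak leaf-area index at flowering (6).
#' @param lai_end Leaf-area index at maturity (2).
#' @param kc Crop coefficient scaling reference evapotranspiration to crop
#'   transpiration demand from the covered ground fraction (1.15).
#' @param harvest_index Base harvest index on final biomass (0.45).
#' @param hi_ceiling Upper bound on dry grain / dry biomass (0.55).
#' @param stem_fraction Stem share of biomass at flowering (0.4).
#' @param soil_evap_coef Bare-soil/pond evaporation as a fraction of reference
#'   evapotranspiration from the uncovered ground fraction (0.6); rainfed
#'   regimes only.
#' @param moisture_content Grain moisture of reported paddy yield (0.14,
#'   i.e. 140 g H2O per kg grain).
#' @return An object of class `crop_params`.
#' @export
crop_params <- function(rue = 2.2, k_ext = 0.5, lai_max = 6, lai_end = 2,
                        kc = 1.15, harvest_index = 0.45, hi_ceiling = 0.55,
                        stem_fraction = 0.4, soil_evap_coef = 0.6,
                        moisture_content = 0.14) {
  stopifnot(rue > 0, k_ext > 0, lai_max > 0, lai_end >= 0, kc > 0,
            harvest_index > 0, harvest_index <= hi_ceiling, hi_ceiling < 1,
            stem_fraction >= 0, stem_fraction <= 1,
            soil_evap_coef >= 0, soil_evap_coef <= 1,
            moisture_content >= 0, moisture_content < 1)
  structure(list(rue = rue, k_ext = k_ext, lai_max = lai_max,
                 lai_end = lai_end, kc = kc, harvest_index = harvest_index,
                 hi_ceiling = hi_ceiling, stem_fraction = stem_fraction,
                 soil_evap_coef = soil_evap_coef,
                 moisture_content = moisture_content),
            class = "crop_params")
}

# Prescribed leaf-area index as a function of DVS.
lai_curve <- function(dvs, crop) {
  ifelse(dvs <= 1, crop$lai_max * pmax(0, dvs),
         crop$lai_max - (crop$lai_max - crop$lai_end) * pmin(dvs - 1, 1))
}

# Hargreaves-type reference evapotranspiration from measured solar radiation
# (no humidity or wind inputs needed), mm d-1.
et_reference <- function(tmean, srad) {
  pmax(0, 0.0135 * (tmean + 17.8) * srad / 2.45)
}

#' Heat-induced spikelet sterility
#'
#' Per-day sterile fraction rises linearly (default 0.10 per degC) with daily
#' maximum temperature above the 35.6 degC critical threshold; the fractions
#' are averaged over the flowering window and clamped to \[0, 1\].
#'
#' @param tmax_window Daily maximum temperatures over the flowering window
#'   (days with DVS in the configured window), degC.
#' @param stress A [stress_params()].
#' @return Sterility fraction in \[0, 1\] (0 for an empty window).
#' @examples
#' heat_sterility(rep(38.6, 5))  # 3 degC excess x 0.10 -> 0.30
#' @export
heat_sterility <- function(tmax_window, stress = stress_params()) {
  if (length(tmax_window) == 0L) return(0)
  daily <- pmin(1, pmax(0, stress$sterility_slope *
                          (tmax_window - stress$t_sterility)))
  min(1, max(0, mean(daily)))
}

# First day index at which `lethal_run` consecutive TRUEs have occurred, or NA.
first_lethal_day <- function(below, run) {
  r <- rle(below)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run)
  if (length(hit) == 0L) return(NA_integer_)
  ends[hit[1L]] - r$lengths[hit[1L]] + run
}

#' Simulate one rice season
#'
#' Runs the daily season model for one crop cycle: phenology (thermal time),
#' prescribed canopy, radiation-limited biomass accumulation scaled by the
#' transpiration ratio from the soil water bucket (forced to 1 for irrigated
#' rice), heat sterility around flowering, and the cold-death rule. Yield is
#' paddy rice at 14% moisture.
#'
#' @param weather Daily weather covering the cycle.
#' @param calendar A [crop_calendar()].
#' @param regime `"irrigated"`, `"rainfed_lowland"`, or `"rainfed_upland"`.
#' @param year Calendar year in which sowing occurs (default: first year of
#'   the weather series).
#' @param soil A [soil_profile()]; defaults to the regime's standard profile
#'   (ignored for irrigated rice).
#' @param stress A [stress_params()].
#' @param crop A [crop_params()].
#' @param phen Calibrated [phenology_params()]; if `NULL`, rates are calibrated
#'   against `calendar` on the supplied weather.
#' @return An object of class `season_result`: a list with `yield_mgha` (paddy,
#'   14% moisture), `biomass_mgha` (dry), `sterility`, `water_stress`
#'   (1 - demand-weighted mean transpiration ratio), `flowering`, `maturity`,
#'   `died`, `regime`, `groundwater_cm`.
#' @export
simulate_season <- function(weather, calendar, regime, year = NULL,
                            soil = NULL, stress = stress_params(),
                            crop = crop_params(), phen = NULL) {
  regime <- match.arg(regime,
                      c("irrigated", "rainfed_lowland", "rainfed_upland"))
  stopifnot(inherits(calendar, "crop_calendar"))
  dates <- as.Date(weather$date)
  if (is.null(year)) year <- as.POSIXlt(dates[1])$year + 1900L
  if (is.null(soil) && regime != "irrigated")
    soil <- soil_profile(if (regime == "rainfed_lowland") "lowland" else "upland")
  if (is.null(phen)) phen <- calibrate_development_rates(weather, calendar)

  start <- as.Date(sprintf("%d-01-01", year)) + (calendar$sowing_doy - 1L)
  ph <- simulate_phenology(weather, start, phen)
  i0 <- match(start, dates)
  n <- ph$days_to_maturity
  w <- weather[i0:(i0 + n - 1L), ]
  dvs <- ph$dvs
  tmean <- (w$tmax + w$tmin) / 2

  # cold death: `lethal_run` consecutive days with mean T below t_lethal
  death_day <- first_lethal_day(tmean < stress$t_lethal, stress$lethal_run)
  died <- !is.na(death_day)
  last <- if (died) death_day else n

  # canopy only in the main field (after transplanting for transplanted rice)
  offset <- calendar$transplanting_doy - calendar$sowing_doy
  lai <- lai_curve(dvs, crop)
  lai[seq_len(n) <= offset] <- 0
  fint <- 1 - exp(-crop$k_ext * lai)

  if (regime == "irrigated") {
    ts <- rep(1, n)
    demand <- rep(0, n)
  } else {
    et0 <- et_reference(tmean, w$srad)
    demand <- crop$kc * fint * et0
    evap <- crop$soil_evap_coef * (1 - fint) * et0
    cap <- capillary_rise(soil$groundwater_cm)
    state <- soil_water_init(soil)
    ts <- numeric(n)
    for (d in seq_len(n)) {
      step <- soil_water_step(state, rain = w$precip[d], irrigation = 0,
                              et_demand = demand[d], capillary = cap,
                              evap_demand = evap[d], soil = soil)
      state <- step$state
      ts[d] <- step$ratio
    }
  }

  live <- seq_len(last)
  db <- crop$rue * stress$par_fraction * w$srad * fint * ts * 0.01 # Mg ha-1
  biomass <- sum(db[live])
  b_fl <- if (ph$days_to_flowering <= last)
    sum(db[seq_len(ph$days_to_flowering)]) else 0

  in_window <- dvs >= stress$dvs_window[1] & dvs <= stress$dvs_window[2] &
    seq_len(n) <= last
  sterility <- heat_sterility(w$tmax[in_window], stress)

  grain_dry <- crop$harvest_index * biomass * (1 - sterility) +
    stress$stem_reserve_fraction * crop$stem_fraction * b_fl
  grain_dry <- min(grain_dry, crop$hi_ceiling * biomass)
  yield <- if (died) 0 else grain_dry / (1 - crop$moisture_content)

  wdem <- sum(demand[live])
  structure(list(yield_mgha = yield, biomass_mgha = biomass,
                 sterility = sterility,
                 water_stress = if (wdem > 0)
                   1 - sum(ts[live] * demand[live]) / wdem else 0,
                 flowering = ph$flowering, maturity = ph$maturity,
                 died = died, regime = regime,
                 groundwater_cm = if (regime == "irrigated") NA_real_
                   else soil$groundwater_cm),
            class = "season_result")
}

#' Simulate a multi-year yield series
#'
#' Runs [simulate_season()] for every year of the weather series in which the
#' crop cycle fits (and every cycle if `calendar` is a list of calendars).
#' Development rates are calibrated once against the full series. Rainfed
#' lowland rice is run under both groundwater scenarios (shallow 40 cm and
#' deep 100 cm) and their 50:50 area-weighted blend is returned alongside each
#' scenario, reflecting the even split of lowland area between favourable and
#' drought-prone water tables.
#'
#' @inheritParams simulate_season
#' @param calendar A [crop_calendar()] or a list of them (one per cycle of the
#'   cropping system).
#' @return A data frame of class `yield_series` with columns `year`, `cycle`,
#'   `regime`, `scenario` (`"main"`, `"shallow"`, `"deep"`, `"blend"`),
#'   `groundwater_cm`, `yield_mgha`, `biomass_mgha`, `sterility`, `died`.
#' @export
simulate_multi_year <- function(weather, calendar, regime, soil = NULL,
                                stress = stress_params(), crop = crop_params(),
                                phen = NULL) {
  regime <- match.arg(regime,
                      c("irrigated", "rainfed_lowland", "rainfed_upland"))
  cycles <- if (inherits(calendar, "crop_calendar")) list(calendar) else calendar
  dates <- as.Date(weather$date)
  yrs <- sort(unique(as.POSIXlt(dates)$year + 1900L))
  if (length(yrs) < 2) stop("need at least 2 years of weather", call. = FALSE)

  rows <- list()
  for (ci in seq_along(cycles)) {
    cal <- cycles[[ci]]
    ph <- if (is.null(phen)) calibrate_development_rates(weather, cal) else phen
    soils <- if (regime == "rainfed_lowland") {
      list(shallow = soil_profile("lowland", groundwater_cm = 40),
           deep = soil_profile("lowland", groundwater_cm = 100))
    } else if (regime == "rainfed_upland") {
      list(main = if (is.null(soil)) soil_profile("upland") else soil)
    } else list(main = NULL)
    for (yr in yrs) {
      res <- lapply(soils, function(sp) {
        tryCatch(simulate_season(weather, cal, regime, year = yr, soil = sp,
                                 stress = stress, crop = crop, phen = ph),
                 error = function(e) NULL)
      })
      if (any(vapply(res, is.null, logical(1)))) next # cycle ran off series end
      for (nm in names(res)) {
        r <- res[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, cycle = ci, regime = regime, scenario = nm,
          groundwater_cm = r$groundwater_cm, yield_mgha = r$yield_mgha,
          biomass_mgha = r$biomass_mgha, sterility = r$sterility,
          died = r$died)
      }
      if (regime == "rainfed_lowland") {
        sh <- res$shallow; dp <- res$deep
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, cycle = ci, regime = regime, scenario = "blend",
          groundwater_cm = NA_real_,
          yield_mgha = 0.5 * (sh$yield_mgha + dp$yield_mgha),
          biomass_mgha = 0.5 * (sh$biomass_mgha + dp$biomass_mgha),
          sterility = 0.5 * (sh$sterility + dp$sterility),
          died = sh$died && dp$died)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no complete crop cycle fits the weather series",
                         call. = FALSE)
  class(out) <- c("yield_series", class(out))
  out
}

#' Annual mean yield of a simulated series
#'
#' Convenience accessor: the per-year yield of the representative scenario
#' (`"blend"` for rainfed lowland, `"main"` otherwise), averaged over cycles.
#'
#' @param series A `yield_series` from [simulate_multi_year()].
#' @return Named numeric vector of yields (Mg ha-1) by year.
#' @export
annual_yield <- function(series) {
  rep_scen <- if (any(series$scenario == "blend")) "blend" else "main"
  s <- series[series$scenario == rep_scen, ]
  tapply(s$yield_mgha, s$year, mean)
}
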