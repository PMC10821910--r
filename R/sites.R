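#' Generate a synthetic site network with country profiles
#'
#' Emulates the study layout the downstream stages expect: each country gets
#' its own monsoonal weather series, crop calendars, one to six reference
#' buffers per present water regime (with harvested areas, climate-zone
#' labels, and sparse pairwise overlaps), and a country profile (production,
#' trade, population, per-capita demand, milling rate, yield trend). Actual
#' farmers' yields are drawn strictly below the attainable yield implied by
#' simulating the generated weather (buffer-level gap fractions of 35-65% of
#' attainable), so every stratum carries a positive exploitable gap, and
#' country production equals the sum of regime area x actual yield, so the
#' baseline accounting identity holds exactly.
#'
#' The whole network is a pure function of `(n_countries, seed, years,
#' params)`.
#'
#' @param n_countries Number of countries to generate (>= 1).
#' @param seed Integer RNG seed.
#' @param years Years of daily weather per country (default 20, the standard
#'   simulation window; shorter windows can be requested).
#' @param params Base [weather_params()]; per-country climate is jittered
#'   around it.
#' @return An object of class `rice_network`: a list with data frames
#'   `buffers`, `overlaps`, `profiles`, `regimes`, `calendars`, a named list
#'   `weather` of per-country daily series, and `years`.
#' @export
gen_site_network <- function(n_countries, seed = 1L, years = 20,
                             params = weather_params()) {
  if (!is.numeric(n_countries) || n_countries < 1)
    stop("n_countries must be >= 1", call. = FALSE)
  n_countries <- as.integer(n_countries)
  regime_levels <- c("irrigated", "rainfed_lowland", "rainfed_upland")

  with_seed(seed, {
    buffers <- list(); overlaps <- list(); profiles <- list()
    regimes <- list(); calendars <- list(); weather <- list()
    for (i in seq_len(n_countries)) {
      cname <- sprintf("C%02d", i)
      cpar <- weather_params(
        mean_temp = params$mean_temp + stats::runif(1, -2.5, 2.5),
        seasonal_amp = params$seasonal_amp,
        diurnal_range = params$diurnal_range + stats::runif(1, -1, 1),
        monsoon_onset = params$monsoon_onset + stats::runif(1, -20, 20),
        monsoon_length = params$monsoon_length + stats::runif(1, -15, 15),
        onset_sd = params$onset_sd, length_sd = params$length_sd,
        p_wet_monsoon = min(1, max(0, params$p_wet_monsoon +
                                     stats::runif(1, -0.1, 0.1))),
        p_wet_dry = params$p_wet_dry,
        wet_depth_mean = params$wet_depth_mean * stats::runif(1, 0.85, 1.15),
        gamma_shape = params$gamma_shape,
        srad_clear = params$srad_clear + stats::runif(1, -2, 2),
        srad_amp = params$srad_amp, rain_atten = params$rain_atten,
        temp_noise_sd = params$temp_noise_sd,
        srad_noise_sd = params$srad_noise_sd)
      wseed <- as.integer((abs(as.numeric(seed)) * 131 + i) %%
                            (.Machine$integer.max - 1L)) + 1L
      w <- gen_weather(cpar, years = years, seed = wseed)
      weather[[cname]] <- w

      present <- regime_levels[stats::runif(3) < c(0.6, 0.8, 0.5)]
      if (length(present) == 0L) present <- "rainfed_lowland"

      sowing <- max(1L, min(180L, round(cpar$monsoon_onset - 10)))
      country_rows <- list()
      for (rg in present) {
        duration <- round(stats::runif(1, 115, 130))
        cal <- crop_calendar(
          establishment = if (rg == "rainfed_upland") "direct-seeded"
                          else "transplanted",
          sowing_doy = sowing,
          transplanting_doy = if (rg == "rainfed_upland") NULL
                              else sowing + 18L,
          maturity_doy = sowing + duration)
        calendars[[length(calendars) + 1L]] <- data.frame(
          country = cname, regime = rg, establishment = cal$establishment,
          sowing_doy = cal$sowing_doy,
          transplanting_doy = cal$transplanting_doy,
          flowering_doy = cal$flowering_doy, maturity_doy = cal$maturity_doy)

        series <- simulate_multi_year(w, cal, rg)
        yp <- mean(annual_yield(series))
        att <- attainable_yield(yp, rg)

        n_buf <- sample.int(6, 1)
        area_ha <- stats::rlnorm(n_buf, meanlog = log(1.5e5), sdlog = 0.6)
        gap_frac <- stats::runif(n_buf, 0.35, 0.65)
        ids <- sprintf("%s_%s_B%d", cname, rg, seq_len(n_buf))
        buffers[[length(buffers) + 1L]] <- data.frame(
          id = ids, country = cname, regime = rg,
          climate_zone = sprintf("%s_CZ%d", cname,
                                 sample.int(3, n_buf, replace = TRUE)),
          area_ha = area_ha, ya_mgha = att * (1 - gap_frac),
          calendar_ref = sprintf("%s_%s", cname, rg))
        if (n_buf > 1L) {
          pairs <- utils::combn(ids, 2)
          pick <- stats::runif(ncol(pairs)) < 0.25
          if (any(pick))
            overlaps[[length(overlaps) + 1L]] <- data.frame(
              id_a = pairs[1, pick], id_b = pairs[2, pick],
              fraction = stats::runif(sum(pick), 0, 0.35))
        }
        b <- buffers[[length(buffers)]]
        country_rows[[rg]] <- data.frame(
          country = cname, regime = rg, area_mha = sum(b$area_ha) / 1e6,
          ya_mgha = area_weighted_mean(b$ya_mgha, b$area_ha),
          yp_mgha = yp, attainable_mgha = att)
      }
      reg <- do.call(rbind, country_rows)
      regimes[[length(regimes) + 1L]] <- reg

      production <- sum(reg$area_mha * reg$ya_mgha) # Mt
      imports <- production * stats::runif(1, 0.1, 0.8)
      exports <- production * stats::runif(1, 0, 0.05)
      stock <- production * stats::runif(1, -0.02, 0.02)
      demand_now <- production + imports - exports - stock
      pc_now <- stats::runif(1, 35, 70)
      pop_now <- demand_now * 1e9 / pc_now
      profiles[[length(profiles) + 1L]] <- data.frame(
        country = cname, production_mt = production, imports_mt = imports,
        exports_mt = exports, stock_change_mt = stock,
        population_now = pop_now,
        population_2050 = pop_now * stats::runif(1, 1.7, 2.2),
        per_capita_now_kg = pc_now,
        per_capita_2050_kg = pc_now * stats::runif(1, 1.05, 1.35),
        milling_rate = stats::runif(1, 0.63, 0.69),
        yield_trend_kg_ha_yr = stats::runif(1, 0, 30))
    }
    structure(list(buffers = do.call(rbind, buffers),
                   overlaps = if (length(overlaps))
                     do.call(rbind, overlaps)
                   else data.frame(id_a = character(), id_b = character(),
                                   fraction = numeric()),
                   profiles = do.call(rbind, profiles),
                   regimes = do.call(rbind, regimes),
                   calendars = do.call(rbind, calendars),
                   weather = weather, years = years),
              class = "rice_network")
  })
}

#' @export
print.rice_network <- function(x, ...) {
  cat(sprintf("rice_network: %d countries, %d buffers, %d country-regime strata, %d y weather\n",
              nrow(x$profiles), nrow(x$buffers), nrow(x$regimes), x$years))
  invisible(x)
}
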