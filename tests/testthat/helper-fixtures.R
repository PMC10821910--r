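# Constant-weather builder for unit tests: n contiguous days from `start`.
const_weather <- function(n, tmax = 29, tmin = 19, srad = 18, precip = 0,
                          start = "2001-01-01") {
  data.frame(date = seq(as.Date(start), by = "day", length.out = n),
             srad = rep_len(srad, n), tmax = rep_len(tmax, n),
             tmin = rep_len(tmin, n), precip = rep_len(precip, n))
}

# Standard test calendar: sow doy 140, transplant +18, mature doy 262.
test_calendar <- function() {
  crop_calendar("transplanted", sowing_doy = 140, transplanting_doy = 158,
                maturity_doy = 262)
}

# Deterministic five-country continent for scenario tests. Country D's
# irrigated stratum has a closed gap (attainable < actual) on purpose.
five_country_regimes <- function() {
  data.frame(
    country = c("A", "A", "B", "B", "C", "D", "D", "E"),
    regime = c("irrigated", "rainfed_lowland", "irrigated", "rainfed_upland",
               "rainfed_lowland", "irrigated", "rainfed_upland",
               "rainfed_lowland"),
    area_mha = c(1.2, 0.8, 0.5, 1.5, 2.0, 0.9, 0.6, 1.0),
    ya_mgha = c(4.5, 2.8, 5.5, 1.4, 2.2, 6.8, 1.1, 3.0),
    attainable_mgha = c(7.9, 5.6, 8.2, 3.1, 5.0, 6.5, 2.9, 5.8))
}

five_country_demand <- function() {
  data.frame(country = c("A", "B", "C", "D", "E"),
             demand_now_mt = c(9.5, 6.0, 6.5, 7.0, 5.0),
             demand_2050_mt = c(22, 15, 18, 12, 14))
}
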