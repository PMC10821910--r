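test_that("heat sterility rises linearly above the critical temperature", {
  expect_equal(heat_sterility(rep(30, 5)), 0)
  expect_equal(heat_sterility(rep(50, 5)), 1)
  expect_equal(heat_sterility(rep(38.6, 5)), 0.30)
  expect_equal(heat_sterility(c(35.6, 36.6)), 0.05)  # window average
  expect_equal(heat_sterility(numeric(0)), 0)
})

test_that("no radiation means no biomass and no yield", {
  w <- const_weather(400, srad = 0)
  cal <- crop_calendar("direct-seeded", sowing_doy = 10, maturity_doy = 130)
  r <- simulate_season(w, cal, "irrigated", year = 2001,
                       phen = phenology_params())
  expect_equal(r$yield_mgha, 0)
  expect_equal(r$biomass_mgha, 0)
})

test_that("three consecutive days below 12 degC mid-season kill the crop", {
  w <- const_weather(400, tmax = 29, tmin = 19)
  cal <- crop_calendar("direct-seeded", sowing_doy = 10, maturity_doy = 130)
  phen <- calibrate_development_rates(w, cal)
  alive <- simulate_season(w, cal, "irrigated", year = 2001, phen = phen)
  expect_false(alive$died)
  expect_gt(alive$yield_mgha, 0)

  w$tmax[60:62] <- 13; w$tmin[60:62] <- 9  # mean 11 degC for 3 days
  dead <- simulate_season(w, cal, "irrigated", year = 2001, phen = phen)
  expect_true(dead$died)
  expect_equal(dead$yield_mgha, 0)

  # two cold days are survivable
  w$tmax[62] <- 29; w$tmin[62] <- 19
  ok <- simulate_season(w, cal, "irrigated", year = 2001, phen = phen)
  expect_false(ok$died)
})

test_that("water limitation and groundwater depth order yields monotonically", {
  w <- gen_weather(weather_params(), years = 6, seed = 11)
  cal <- test_calendar()
  phen <- calibrate_development_rates(w, cal)
  for (yr in 2000:2004) {
    yp <- simulate_season(w, cal, "irrigated", year = yr, phen = phen)
    y40 <- simulate_season(w, cal, "rainfed_lowland", year = yr, phen = phen,
                           soil = soil_profile("lowland", groundwater_cm = 40))
    y100 <- simulate_season(w, cal, "rainfed_lowland", year = yr, phen = phen,
                            soil = soil_profile("lowland", groundwater_cm = 100))
    y1000 <- simulate_season(w, cal, "rainfed_lowland", year = yr, phen = phen,
                             soil = soil_profile("lowland", groundwater_cm = 1000))
    expect_gte(yp$yield_mgha, y40$yield_mgha - 1e-9)
    expect_gte(y40$yield_mgha, y100$yield_mgha - 1e-9)
    expect_gte(y100$yield_mgha, y1000$yield_mgha - 1e-9)
  }
})

test_that("scaling precipitation down never increases rainfed yield", {
  w <- gen_weather(weather_params(), years = 4, seed = 13)
  cal <- test_calendar()
  phen <- calibrate_development_rates(w, cal)
  for (regime in c("rainfed_lowland", "rainfed_upland")) {
    prev <- -Inf
    for (k in c(0, 0.3, 0.7, 1)) {
      wk <- w
      wk$precip <- w$precip * k
      y <- simulate_season(wk, cal, regime, year = 2001, phen = phen)
      expect_gte(y$yield_mgha, prev - 1e-9)
      prev <- y$yield_mgha
    }
  }
})

test_that("identical weather years give identical yields and the stated lowland blend", {
  one <- const_weather(365, tmax = 30, tmin = 20, srad = 17,
                       precip = rep(c(8, 0), length.out = 365),
                       start = "2001-01-01")
  two <- one
  two$date <- seq(as.Date("2002-01-01"), by = "day", length.out = 365)
  w <- rbind(one, two)
  cal <- test_calendar()
  s <- simulate_multi_year(w, cal, "rainfed_lowland")
  ys <- s[s$scenario == "shallow", ]
  yd <- s[s$scenario == "deep", ]
  yb <- s[s$scenario == "blend", ]
  expect_equal(nrow(yb), 2)
  # identical years -> identical seasons
  expect_equal(ys$yield_mgha[1], ys$yield_mgha[2])
  expect_equal(yd$yield_mgha[1], yd$yield_mgha[2])
  # 50:50 groundwater-scenario blend, year by year
  expect_equal(yb$yield_mgha, 0.5 * (ys$yield_mgha + yd$yield_mgha))
  expect_equal(yb$biomass_mgha, 0.5 * (ys$biomass_mgha + yd$biomass_mgha))
})

test_that("season results respect the harvest-index ceiling and report paddy moisture", {
  w <- gen_weather(weather_params(), years = 3, seed = 21)
  cal <- test_calendar()
  crop <- crop_params()
  r <- simulate_season(w, cal, "irrigated", year = 2001, phen = NULL,
                       crop = crop)
  expect_gte(r$yield_mgha, 0)
  # dry grain (yield at 14% moisture x 0.86) never exceeds ceiling x biomass
  expect_lte(r$yield_mgha * (1 - crop$moisture_content),
             crop$hi_ceiling * r$biomass_mgha + 1e-9)
  expect_gte(r$sterility, 0); expect_lte(r$sterility, 1)
  expect_gte(r$water_stress, 0); expect_lte(r$water_stress, 1)
})

test_that("a cycle that runs off the weather series raises a cycle-incomplete error", {
  w <- const_weather(120, tmax = 29, tmin = 19, start = "2001-01-01")
  cal <- crop_calendar("direct-seeded", sowing_doy = 100, maturity_doy = 220)
  expect_error(simulate_season(w, cal, "irrigated", year = 2001,
                               phen = phenology_params()),
               "incomplete")
})
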