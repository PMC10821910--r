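# Straight-line ledger recomputation of one grid cell from the country table,
# written independently of the package internals.
ledger_cell <- function(reg, dem, f, rate, horizon = 30, price = 289,
                        mult = 1.05, ypd = 0, ad = 0, rest = 0) {
  a0 <- sum(reg$area_mha)
  scale <- (a0 + rate * (1 + ad) * horizon) / a0
  prod <- 0; base_y <- 0; new_y <- 0
  for (i in seq_len(nrow(reg))) {
    att <- reg$attainable_mgha[i] * (1 + ypd)
    head <- att - reg$ya_mgha[i]
    if (head < 0) head <- 0
    y <- reg$ya_mgha[i] + f * head
    prod <- prod + reg$area_mha[i] * scale * y
    base_y <- base_y + reg$area_mha[i] * reg$ya_mgha[i]
    new_y <- new_y + reg$area_mha[i] * y
  }
  frac <- if (horizon >= 30) 1 else horizon / 30
  demand <- 0
  for (j in seq_len(nrow(dem)))
    demand <- demand + dem$demand_now_mt[j] +
      (dem$demand_2050_mt[j] - dem$demand_now_mt[j]) * frac
  demand <- demand * mult
  prod <- prod + rest * (new_y / base_y)
  imp <- max(0, demand - prod)
  list(production = prod, demand = demand, ssr = prod / demand,
       net_import = imp, cost = imp * price / 1000)
}

test_that("intensified yield interpolates between actual and attainable", {
  expect_equal(intensified_yield(3, 6, 0), 3)
  expect_equal(intensified_yield(3, 6, 1), 6)
  expect_equal(intensified_yield(2.9, 6.04, 1), 6.04)
  expect_equal(intensified_yield(7, 6, 1), 7)  # closed gap: no headroom
  expect_error(intensified_yield(3, 6, 1.2), "\\[0, 1\\]")
})

test_that("required gain rate scales the headroom over the horizon", {
  expect_equal(required_gain_rate(3, 6, 0, 30), 0)
  expect_equal(required_gain_rate(3, 6, 1, 30), 100)
  expect_equal(required_gain_rate(3, 6, 0.5, 30), 50)
  expect_equal(required_gain_rate(7, 6, 1, 30), 0)  # closed gap
})

test_that("area expansion arithmetic", {
  e <- expanded_area(15, 0.6, 30)
  expect_equal(e$total_mha, 33)
  e2 <- expanded_area(15, 0.4, 30)
  expect_equal(e2$added_mha, 12)
  expect_equal(expanded_area(15, 0, 30)$total_mha, 15)
})

test_that("country production sums regime area x yield", {
  expect_equal(country_production(c(irrigated = 10), c(irrigated = 3)), 30)
  expect_equal(country_production(c(a = 2, b = 1), c(a = 5, b = 2)), 12)
  expect_equal(country_production(c(a = 4, b = 2), c(a = 5, b = 2)),
               2 * country_production(c(a = 2, b = 1), c(a = 5, b = 2)))
  expect_error(country_production(c(a = 1), c(b = 1)), "regimes")
})

test_that("net import, cost, and land equivalent arithmetic", {
  r <- net_import_and_cost(35, 10, 289)
  expect_equal(r$net_import_mt, 25)
  expect_equal(r$cost_usd_b, 25 * 289 / 1000)  # ~7.2 billion
  r2 <- net_import_and_cost(10, 12, 289)
  expect_equal(r2$net_import_mt, 0)
  expect_equal(r2$cost_usd_b, 0)
  expect_equal(net_import_and_cost(77, 10, 289)$cost_usd_b, 67 * 0.289)

  expect_equal(land_equivalent(30, 3), 10)
  expect_equal(land_equivalent(0, 2.9), 0)
  expect_error(land_equivalent(10, 0), "> 0")
})

test_that("the identity cell reproduces the baseline of the input table", {
  reg <- five_country_regimes()
  dem <- five_country_demand()
  spec <- scenario_spec(horizon_years = 0, demand_multiplier = 1)
  cell <- continental_rollup(reg, dem, f = 0, expansion_rate = 0, spec = spec)
  expect_equal(cell$production_mt, sum(reg$area_mha * reg$ya_mgha))
  expect_equal(cell$demand_mt, sum(dem$demand_now_mt))
  expect_equal(cell$ssr,
               sum(reg$area_mha * reg$ya_mgha) / sum(dem$demand_now_mt))
  expect_equal(cell$added_area_mha, 0)
})

test_that("the continental demand multiplier scales pooled demand", {
  reg <- five_country_regimes()
  dem <- five_country_demand()
  dem$demand_2050_mt <- dem$demand_now_mt  # flat demand to isolate the factor
  dem$demand_now_mt <- c(20, 20, 20, 20, 20)
  dem$demand_2050_mt <- dem$demand_now_mt
  cell <- continental_rollup(reg, dem, 0, 0,
                             scenario_spec(demand_multiplier = 1.05))
  expect_equal(cell$demand_mt, 105)
})

test_that("a three-country cell equals a hand-computed pooled ledger", {
  reg <- data.frame(country = c("P", "Q", "R"),
                    regime = c("irrigated", "rainfed_lowland",
                               "rainfed_upland"),
                    area_mha = c(1, 2, 1), ya_mgha = c(4, 2, 1),
                    attainable_mgha = c(8, 5, 3))
  dem <- data.frame(country = c("P", "Q", "R"),
                    demand_now_mt = c(6, 5, 3),
                    demand_2050_mt = c(12, 11, 7))
  spec <- scenario_spec(demand_multiplier = 1.05)
  cell <- continental_rollup(reg, dem, f = 0.5, expansion_rate = 0.1,
                             spec = spec, rest_production_mt = 2)
  # by hand: areas scale by (4 + 3)/4 = 1.75;
  # yields 4+2=6, 2+1.5=3.5, 1+1=2 -> production 1.75*(6 + 7 + 2) = 26.25
  # rest factor = (6 + 7 + 2)/(4 + 4 + 1) = 15/9; production += 2*15/9
  # demand = (12 + 11 + 7) * 1.05 = 31.5
  expect_equal(cell$production_mt, 1.75 * 15 + 2 * 15 / 9)
  expect_equal(cell$demand_mt, 31.5)
  expect_equal(cell$net_import_mt, max(0, 31.5 - cell$production_mt))
  expect_equal(cell$import_cost_usd_b, cell$net_import_mt * 289 / 1000)
})

test_that("every grid cell matches the independent ledger oracle", {
  reg <- five_country_regimes()
  dem <- five_country_demand()
  grid <- run_scenario_grid(reg, dem, f_values = c(0, 0.25, 0.5, 1),
                            rates = c(0.2, 0.4, 0.6),
                            rest_production_mt = 1.5)
  for (i in seq_len(nrow(grid))) {
    o <- ledger_cell(reg, dem, grid$f[i], grid$expansion_rate[i], rest = 1.5)
    expect_equal(grid$production_mt[i], o$production)
    expect_equal(grid$demand_mt[i], o$demand)
    expect_equal(grid$ssr[i], o$ssr)
    expect_equal(grid$net_import_mt[i], o$net_import)
    expect_equal(grid$import_cost_usd_b[i], o$cost)
    # ledger closure: demand - production = net import - net export
    expect_equal(grid$demand_mt[i] - grid$production_mt[i],
                 grid$net_import_mt[i] - grid$net_export_mt[i])
  }
})

test_that("SSR is monotone in closure fraction and expansion rate", {
  grid <- run_scenario_grid(five_country_regimes(), five_country_demand(),
                            f_values = seq(0, 1, 0.1), rates = c(0.2, 0.4, 0.6))
  for (r in unique(grid$expansion_rate)) {
    g <- grid[grid$expansion_rate == r, ]
    g <- g[order(g$f), ]
    expect_true(all(diff(g$ssr) >= -1e-12))
  }
  for (fv in unique(grid$f)) {
    g <- grid[grid$f == fv, ]
    g <- g[order(g$expansion_rate), ]
    expect_true(all(diff(g$ssr) >= -1e-12))
  }
})

test_that("climate sensitivity scales the right components", {
  reg <- five_country_regimes()
  dem <- five_country_demand()
  grid <- run_scenario_grid(reg, dem, f_values = c(0, 0.5, 1),
                            rates = c(0.2, 0.4))
  same <- climate_sensitivity(grid, 0, 0)
  for (col in c("production_mt", "demand_mt", "ssr", "net_import_mt"))
    expect_equal(same[[col]], grid[[col]])

  # one-country fixture with ya = 0: at f = 1 production comes entirely from
  # the intensified (attainable) component, so -10% on yield potential scales
  # production by exactly 0.90
  one <- data.frame(country = "Z", regime = "irrigated", area_mha = 1,
                    ya_mgha = 0, attainable_mgha = 8)
  dem1 <- data.frame(country = "Z", demand_now_mt = 10, demand_2050_mt = 10)
  g1 <- run_scenario_grid(one, dem1, f_values = 1, rates = 0)
  g1d <- climate_sensitivity(g1, yp_delta = -0.10, area_delta = 0)
  expect_equal(g1d$production_mt, 0.90 * g1$production_mt)

  # SSR never increases as the deltas grow in magnitude
  worse <- climate_sensitivity(grid, -0.10, -0.10)
  expect_true(all(worse$ssr <= grid$ssr + 1e-12))
  expect_error(climate_sensitivity(grid, -0.2, 0), "deltas")
})

test_that("the closure fraction that zeroes imports is recoverable on a known continent", {
  reg <- five_country_regimes()
  spec <- scenario_spec(demand_multiplier = 1)
  f_star <- 0.6
  target <- continental_rollup(reg, five_country_demand(), f_star, 0.4,
                               spec = spec)$production_mt
  dem <- five_country_demand()
  dem$demand_2050_mt <- dem$demand_2050_mt *
    target / sum(dem$demand_2050_mt)  # total 2050 demand = production at f*
  grid <- run_scenario_grid(reg, dem, f_values = seq(0, 1, 0.01),
                            rates = 0.4, spec = spec)
  f_hat <- min(grid$f[grid$net_import_mt <= 1e-9])
  expect_equal(f_hat, f_star, tolerance = 0.011)
})
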