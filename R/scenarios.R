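#' Scenario specification for the 2050 assessment
#'
#' Fixed economic and structural assumptions of the intensification x
#' area-expansion grid: a 30-year horizon, the 2018-2020 world rice price of
#' US$289 per Mg paddy, the 1.05 continental demand multiplier covering
#' countries without demand projections, and optional climate-sensitivity
#' deltas applied to attainable yields and the expansion rate.
#'
#' @param horizon_years Scenario horizon, years (30).
#' @param price_usd_mg Rice market price, US$ per Mg paddy (289).
#' @param demand_multiplier Continental demand multiplier (1.05).
#' @param yp_delta Relative change in attainable yield (0, -0.05, -0.10).
#' @param area_delta Relative change in the expansion rate (0, -0.05, -0.10).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(horizon_years = 30, price_usd_mg = 289,
                          demand_multiplier = 1.05, yp_delta = 0,
                          area_delta = 0) {
  stopifnot(horizon_years >= 0, price_usd_mg > 0, demand_multiplier > 0,
            yp_delta >= -1, yp_delta <= 0, area_delta >= -1, area_delta <= 0)
  structure(list(horizon_years = horizon_years, price_usd_mg = price_usd_mg,
                 demand_multiplier = demand_multiplier, yp_delta = yp_delta,
                 area_delta = area_delta),
            class = "scenario_spec")
}

#' Yield under partial closure of the exploitable gap
#'
#' @param ya Actual yield, Mg ha-1; vectorised.
#' @param attainable Attainable yield, Mg ha-1.
#' @param f Closure fraction of the exploitable gap in \[0, 1\].
#' @return `ya + f * max(0, attainable - ya)`, Mg ha-1. Closed gaps
#'   (`attainable < ya`) contribute no headroom.
#' @export
intensified_yield <- function(ya, attainable, f) {
  if (any(f < 0) || any(f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  ya + f * pmax(0, attainable - ya)
}

#' Rate of yield gain required to close the gap
#'
#' @inheritParams intensified_yield
#' @param horizon_years Years over which the gap is closed (> 0).
#' @return Required yield-gain rate, kg ha-1 yr-1:
#'   `1000 * f * max(0, attainable - ya) / horizon_years`.
#' @examples
#' required_gain_rate(2.9, 2.9 / 0.48, 1, 30)    # ~104.7 (full closure)
#' required_gain_rate(2.9, 2.9 / 0.48, 0.5, 30)  # ~52.4 (half closure)
#' @export
required_gain_rate <- function(ya, attainable, f, horizon_years) {
  if (any(horizon_years <= 0)) stop("horizon_years must be > 0", call. = FALSE)
  1000 * f * pmax(0, attainable - ya) / horizon_years
}

#' Linear harvested-area expansion
#'
#' @param area0 Current harvested area, M ha.
#' @param rate Annual expansion rate, M ha yr-1 (>= 0).
#' @param years Horizon, years (>= 0).
#' @return List with `total_mha` (`area0 + rate * years`) and `added_mha`
#'   (`rate * years`).
#' @examples
#' expanded_area(15, 0.6, 30)  # 33 M ha total, 18 added
#' @export
expanded_area <- function(area0, rate, years) {
  if (any(rate < 0) || any(years < 0))
    stop("rate and years must be >= 0", call. = FALSE)
  list(total_mha = area0 + rate * years, added_mha = rate * years)
}

#' National production from regime areas and yields
#'
#' @param areas_mha Named vector of harvested areas by regime, M ha.
#' @param yields_mgha Named vector of yields by regime, Mg ha-1 (same regimes).
#' @return Production, Mt (`sum(area * yield)`).
#' @export
country_production <- function(areas_mha, yields_mgha) {
  if (!setequal(names(areas_mha), names(yields_mgha)) ||
      is.null(names(areas_mha)))
    stop("areas and yields must cover the same named regimes", call. = FALSE)
  sum(areas_mha * yields_mgha[names(areas_mha)])
}

#' Net rice import and its cost
#'
#' @param demand,production Mt paddy yr-1.
#' @param price_usd_mg Price, US$ per Mg paddy (> 0).
#' @return List with `net_import_mt` (`max(0, demand - production)`) and
#'   `cost_usd_b` (import x price / 1000, billion US$).
#' @examples
#' net_import_and_cost(35, 10, 289)  # 25 Mt, ~7.2 billion US$
#' @export
net_import_and_cost <- function(demand, production, price_usd_mg = 289) {
  if (any(price_usd_mg <= 0)) stop("price must be > 0", call. = FALSE)
  imp <- pmax(0, demand - production)
  list(net_import_mt = imp, cost_usd_b = imp * price_usd_mg / 1000)
}

#' Land equivalent of a rice deficit
#'
#' @param deficit_mt Deficit, Mt paddy yr-1.
#' @param yield_mgha Yield at which new land would produce, Mg ha-1 (> 0).
#' @return Equivalent new harvested area, M ha (`deficit / yield`).
#' @examples
#' land_equivalent(67, 2.9)  # ~23.1 M ha
#' @export
land_equivalent <- function(deficit_mt, yield_mgha) {
  if (any(yield_mgha <= 0)) stop("yield must be > 0", call. = FALSE)
  deficit_mt / yield_mgha
}

#' Continental roll-up for one scenario cell
#'
#' Pools the study countries (regional trade offsets national deficits with
#' surpluses elsewhere): intensified yields are `ya + f x headroom` with
#' attainable yields scaled by `1 + yp_delta`; expansion (rate scaled by
#' `1 + area_delta`) is allocated pro-rata to current area across countries
#' and regimes; demand interpolates linearly from the baseline to the 2050
#' projection over a 30-year span and is multiplied by the continental
#' `demand_multiplier`. Rest-of-continent production (countries outside the
#' study set) is the supplied baseline scaled under `rest_mode`:
#' `"yield_ratio"` (default) applies the study-average relative yield
#' increase, `"production_ratio"` the study-average relative production
#' increase (includes expansion), `"none"` leaves it at baseline.
#'
#' @param regimes Data frame with columns `country`, `regime`, `area_mha`,
#'   `ya_mgha`, `attainable_mgha` (one row per country x regime stratum).
#' @param demand Data frame with columns `country`, `demand_now_mt`,
#'   `demand_2050_mt`.
#' @param f Closure fraction of the exploitable gap in \[0, 1\].
#' @param expansion_rate Area expansion rate, M ha yr-1.
#' @param spec A [scenario_spec()].
#' @param rest_production_mt Baseline rest-of-continent production, Mt.
#' @param rest_mode `"yield_ratio"`, `"production_ratio"`, or `"none"`.
#' @return One-row data frame: `f`, `expansion_rate`, `production_mt`,
#'   `demand_mt`, `ssr`, `net_import_mt`, `net_export_mt`,
#'   `import_cost_usd_b`, `added_area_mha`.
#' @export
continental_rollup <- function(regimes, demand, f, expansion_rate,
                               spec = scenario_spec(),
                               rest_production_mt = 0,
                               rest_mode = c("yield_ratio", "production_ratio",
                                             "none")) {
  rest_mode <- match.arg(rest_mode)
  stopifnot(all(c("country", "regime", "area_mha", "ya_mgha",
                  "attainable_mgha") %in% names(regimes)),
            all(c("country", "demand_now_mt", "demand_2050_mt") %in%
                  names(demand)))
  att <- regimes$attainable_mgha * (1 + spec$yp_delta)
  rate <- expansion_rate * (1 + spec$area_delta)
  added <- rate * spec$horizon_years
  a0 <- sum(regimes$area_mha)
  area <- regimes$area_mha * (a0 + added) / a0
  yld <- intensified_yield(regimes$ya_mgha, att, f)
  prod_study <- sum(area * yld)

  frac <- if (spec$horizon_years >= 30) 1 else spec$horizon_years / 30
  dem_country <- demand$demand_now_mt +
    (demand$demand_2050_mt - demand$demand_now_mt) * frac
  dem <- sum(dem_country) * spec$demand_multiplier

  rest_factor <- switch(rest_mode,
    yield_ratio = sum(regimes$area_mha * yld) / sum(regimes$area_mha *
                                                      regimes$ya_mgha),
    production_ratio = prod_study / sum(regimes$area_mha * regimes$ya_mgha),
    none = 1)
  production <- prod_study + rest_production_mt * rest_factor

  imp <- net_import_and_cost(dem, production, spec$price_usd_mg)
  data.frame(f = f, expansion_rate = expansion_rate,
             production_mt = production, demand_mt = dem,
             ssr = self_sufficiency_ratio(production, dem),
             net_import_mt = imp$net_import_mt,
             net_export_mt = max(0, production - dem),
             import_cost_usd_b = imp$cost_usd_b,
             added_area_mha = added)
}

#' Run the intensification x expansion scenario grid
#'
#' One [continental_rollup()] per (closure fraction, expansion rate) cell.
#'
#' @inheritParams continental_rollup
#' @param f_values Closure fractions (default 0 to 1 by 0.1).
#' @param rates Expansion rates, M ha yr-1 (default 0.2, 0.4, 0.6).
#' @return Data frame of `ScenarioResult` rows, one per grid cell, carrying
#'   its inputs as an attribute so that [climate_sensitivity()] can recompute
#'   the grid under perturbed assumptions.
#' @export
run_scenario_grid <- function(regimes, demand, f_values = seq(0, 1, by = 0.1),
                              rates = c(0.2, 0.4, 0.6),
                              spec = scenario_spec(),
                              rest_production_mt = 0,
                              rest_mode = "yield_ratio") {
  cells <- expand.grid(f = f_values, expansion_rate = rates,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i)
    continental_rollup(regimes, demand, cells$f[i], cells$expansion_rate[i],
                       spec, rest_production_mt, rest_mode))
  grid <- do.call(rbind, rows)
  attr(grid, "inputs") <- list(regimes = regimes, demand = demand,
                               f_values = f_values, rates = rates,
                               spec = spec,
                               rest_production_mt = rest_production_mt,
                               rest_mode = rest_mode)
  grid
}

#' Climate-sensitivity adjustment of a scenario grid
#'
#' Recomputes a grid produced by [run_scenario_grid()] with attainable yields
#' scaled by `1 + yp_delta` (before gap closure) and the expansion rate scaled
#' by `1 + area_delta`.
#'
#' @param grid Output of [run_scenario_grid()].
#' @param yp_delta,area_delta Relative reductions in \[-0.10, 0\].
#' @return The adjusted grid (same cells, recomputed results).
#' @export
climate_sensitivity <- function(grid, yp_delta = 0, area_delta = 0) {
  inputs <- attr(grid, "inputs")
  if (is.null(inputs))
    stop("grid must come from run_scenario_grid()", call. = FALSE)
  if (yp_delta < -0.10 || yp_delta > 0 || area_delta < -0.10 || area_delta > 0)
    stop("deltas must lie in [-0.10, 0]", call. = FALSE)
  spec <- inputs$spec
  spec$yp_delta <- yp_delta
  spec$area_delta <- area_delta
  run_scenario_grid(inputs$regimes, inputs$demand, inputs$f_values,
                    inputs$rates, spec, inputs$rest_production_mt,
                    inputs$rest_mode)
}
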