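#' Baseline national rice demand from the accounting identity
#'
#' Demand = production + imports - exports - stock change, all on a paddy
#' basis. A positive stock change means stocks were built up (grain withheld
#' from consumption) and is therefore subtracted.
#'
#' @param production,imports,exports Mt paddy yr-1 (all >= 0); vectorised.
#' @param stock_change Mt paddy yr-1 (may be negative: stock drawdown).
#' @return Demand, Mt paddy yr-1.
#' @export
baseline_demand <- function(production, imports, exports, stock_change = 0) {
  if (any(production < 0) || any(imports < 0) || any(exports < 0))
    stop("production, imports and exports must be >= 0", call. = FALSE)
  demand <- production + imports - exports - stock_change
  if (any(demand < 0))
    stop("accounting error: negative demand", call. = FALSE)
  demand
}

#' Convert milled-rice quantities to paddy basis
#'
#' Divides milled rice by the country's milling rate. Milling rates outside
#' the typical 0.63-0.69 range draw a warning.
#'
#' @param milled Milled-rice quantity (e.g. kg per capita); vectorised.
#' @param milling_rate Milling rate in (0, 1\].
#' @return Paddy-basis quantity.
#' @examples
#' milled_to_paddy(40, 0.66)  # 60.6 kg paddy
#' @export
milled_to_paddy <- function(milled, milling_rate) {
  if (any(milling_rate <= 0) || any(milling_rate > 1))
    stop("milling rate must lie in (0, 1]", call. = FALSE)
  if (any(milling_rate < 0.63 | milling_rate > 0.69))
    warning("milling rate outside the typical 0.63-0.69 range", call. = FALSE)
  milled / milling_rate
}

#' Project total rice demand from population and per-capita demand
#'
#' @param population Persons (> 0); vectorised.
#' @param per_capita Per-capita rice demand, kg paddy person-1 yr-1.
#' @return Total demand, Mt paddy yr-1 (`population * per_capita / 1e9`).
#' @examples
#' project_demand(2.5e9, 60)  # 150 Mt
#' @export
project_demand <- function(population, per_capita) {
  if (any(population < 0) || any(per_capita < 0))
    stop("inputs must be non-negative", call. = FALSE)
  population * per_capita / 1e9
}

#' Extrapolate yield along the historical trend, capped at attainable
#'
#' Continues the historical linear yield trend for `years` years, never
#' exceeding the attainable-yield cap. If the cap is already below the current
#' yield (gap closed), the current yield is returned with a warning.
#'
#' @param y0 Current yield, Mg ha-1; vectorised.
#' @param trend Historical yield trend, kg ha-1 yr-1.
#' @param years Extrapolation horizon, years (>= 0).
#' @param cap Attainable yield, Mg ha-1.
#' @return Extrapolated yield, Mg ha-1.
#' @export
extrapolate_yield <- function(y0, trend, years, cap) {
  if (any(years < 0)) stop("years must be >= 0", call. = FALSE)
  closed <- cap < y0
  if (any(closed))
    warning("attainable cap below current yield (gap already closed); returning current yield",
            call. = FALSE)
  ifelse(closed, y0, pmin(y0 + trend * years / 1000, cap))
}

#' Self-sufficiency ratio and rice deficit
#'
#' `self_sufficiency_ratio()` is production over demand;
#' `rice_deficit()` is demand minus production (negative values are an
#' exportable surplus).
#'
#' @param production,demand Mt paddy yr-1 (`demand > 0` for the SSR);
#'   vectorised.
#' @return Ratio, or deficit in Mt paddy yr-1.
#' @export
self_sufficiency_ratio <- function(production, demand) {
  if (any(demand <= 0)) stop("demand must be > 0", call. = FALSE)
  production / demand
}

#' @rdname self_sufficiency_ratio
#' @export
rice_deficit <- function(demand, production) {
  demand - production
}

#' Country-level demand records and 2050 projection
#'
#' Builds one record per country from its profile: baseline demand from the
#' accounting identity, 2050 demand from projected population and per-capita
#' demand (paddy basis), extrapolated 2050 production (historical yield trend
#' capped at the attainable yield, current area), SSR now and in 2050, and the
#' 2050 deficit.
#'
#' @param profiles Data frame with columns `country`, `production_mt`,
#'   `imports_mt`, `exports_mt`, `stock_change_mt`, `population_2050`,
#'   `per_capita_2050_kg`, `yield_trend_kg_ha_yr`.
#' @param regimes Data frame with columns `country`, `regime`, `area_mha`,
#'   `ya_mgha`, `attainable_mgha`.
#' @param horizon_years Projection horizon, years (30).
#' @return Data frame with one row per country: `demand_now_mt`,
#'   `demand_2050_mt`, `production_2050_mt`, `ssr_now`, `ssr_2050`,
#'   `deficit_2050_mt`.
#' @export
project_countries <- function(profiles, regimes, horizon_years = 30) {
  stopifnot(all(c("country", "production_mt", "imports_mt", "exports_mt",
                  "stock_change_mt", "population_2050", "per_capita_2050_kg",
                  "yield_trend_kg_ha_yr") %in% names(profiles)))
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    reg <- regimes[regimes$country == p$country, ]
    demand_now <- baseline_demand(p$production_mt, p$imports_mt, p$exports_mt,
                                  p$stock_change_mt)
    demand_2050 <- project_demand(p$population_2050, p$per_capita_2050_kg)
    y2050 <- extrapolate_yield(reg$ya_mgha, p$yield_trend_kg_ha_yr,
                               horizon_years, reg$attainable_mgha)
    production_2050 <- sum(reg$area_mha * y2050)
    data.frame(country = p$country, demand_now_mt = demand_now,
               demand_2050_mt = demand_2050,
               production_now_mt = p$production_mt,
               production_2050_mt = production_2050,
               ssr_now = self_sufficiency_ratio(p$production_mt, demand_now),
               ssr_2050 = self_sufficiency_ratio(production_2050, demand_2050),
               deficit_2050_mt = rice_deficit(demand_2050, production_2050))
  })
  do.call(rbind, out)
}
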