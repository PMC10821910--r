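#' Configuration of a pipeline run
#'
#' A run is reproducible from `(config)` alone: every stage derives all of its
#' randomness from `seed` and reads/writes CSV tables under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_countries Countries in the synthetic study set.
#' @param years Years of daily weather per country.
#' @param weather Base [weather_params()].
#' @param f_values Closure fractions of the scenario grid.
#' @param rates Expansion rates, M ha yr-1.
#' @param spec A [scenario_spec()].
#' @param deltas Climate-sensitivity deltas applied pairwise to attainable
#'   yield and expansion rate.
#' @param rest_production_mt Baseline rest-of-continent production, Mt.
#' @param rest_mode Rest-of-continent scaling mode (see
#'   [continental_rollup()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_countries = 15, years = 10,
                       weather = weather_params(),
                       f_values = seq(0, 1, by = 0.1),
                       rates = c(0.2, 0.4, 0.6),
                       spec = scenario_spec(),
                       deltas = c(0, -0.05, -0.10),
                       rest_production_mt = 0,
                       rest_mode = "yield_ratio") {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_countries = n_countries, years = years, weather = weather,
                 f_values = f_values, rates = rates, spec = spec,
                 deltas = deltas, rest_production_mt = rest_production_mt,
                 rest_mode = rest_mode),
            class = "run_config")
}

pipeline_path <- function(config, name) file.path(config$out_dir, name)

read_table <- function(config, name) {
  path <- pipeline_path(config, name)
  if (!file.exists(path))
    stop(sprintf("required table '%s' not found", name), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

write_table <- function(df, config, name) {
  utils::write.csv(df, pipeline_path(config, name), row.names = FALSE,
                   quote = FALSE)
}

stage_synth <- function(config) {
  net <- gen_site_network(config$n_countries, seed = config$seed,
                          years = config$years, params = config$weather)
  write_table(net$buffers, config, "buffers.csv")
  write_table(net$overlaps, config, "overlaps.csv")
  write_table(net$profiles, config, "profiles.csv")
  write_table(net$regimes[, c("country", "regime", "area_mha", "ya_mgha")],
              config, "regimes.csv")
  write_table(net$calendars, config, "calendars.csv")
  for (cn in names(net$weather))
    write_weather_csv(net$weather[[cn]],
                      pipeline_path(config, sprintf("weather_%s.csv", cn)))
  invisible(net)
}

stage_simulate <- function(config) {
  calendars <- read_table(config, "calendars.csv")
  seasons <- list(); yields <- list()
  for (i in seq_len(nrow(calendars))) {
    cl <- calendars[i, ]
    wpath <- pipeline_path(config, sprintf("weather_%s.csv", cl$country))
    if (!file.exists(wpath))
      stop(sprintf("weather file for %s not found", cl$country), call. = FALSE)
    w <- qc_fill(read_weather_csv(wpath))
    cal <- crop_calendar(establishment = cl$establishment,
                         sowing_doy = cl$sowing_doy,
                         transplanting_doy = cl$transplanting_doy,
                         maturity_doy = cl$maturity_doy,
                         flowering_doy = cl$flowering_doy)
    series <- simulate_multi_year(w, cal, cl$regime)
    series$country <- cl$country
    seasons[[i]] <- series
    ann <- annual_yield(series)
    stab <- stability_metrics(ann)
    yields[[i]] <- data.frame(country = cl$country, regime = cl$regime,
                              yp_mgha = mean(ann), cv_pct = stab$cv,
                              semidev_mgha = stab$semidev)
  }
  write_table(do.call(rbind, seasons), config, "seasons.csv")
  write_table(do.call(rbind, yields), config, "yields.csv")
  invisible(NULL)
}

stage_gaps <- function(config) {
  yields <- read_table(config, "yields.csv")
  regimes <- read_table(config, "regimes.csv")
  gaps <- merge(regimes, yields, by = c("country", "regime"))
  gaps$attainable_mgha <- attainable_yield(gaps$yp_mgha, gaps$regime)
  eg <- exploitable_gap(gaps$attainable_mgha, gaps$ya_mgha)
  gaps$gap_mgha <- eg$gap
  gaps$gap_fraction <- eg$gap_fraction
  gaps$closed <- eg$closed
  write_table(gaps, config, "gaps.csv")

  w <- gaps$area_mha
  by_regime <- do.call(rbind, lapply(split(gaps, gaps$regime), function(g)
    data.frame(stratum = g$regime[1],
               yp_mgha = area_weighted_mean(g$yp_mgha, g$area_mha),
               ya_mgha = area_weighted_mean(g$ya_mgha, g$area_mha),
               gap_fraction = area_weighted_mean(g$gap_fraction, g$area_mha),
               cv_pct = area_weighted_mean(g$cv_pct, g$area_mha),
               semidev_mgha = area_weighted_mean(g$semidev_mgha, g$area_mha))))
  all_row <- data.frame(stratum = "all",
                        yp_mgha = area_weighted_mean(gaps$yp_mgha, w),
                        ya_mgha = area_weighted_mean(gaps$ya_mgha, w),
                        gap_fraction = area_weighted_mean(gaps$gap_fraction, w),
                        cv_pct = area_weighted_mean(gaps$cv_pct, w),
                        semidev_mgha = area_weighted_mean(gaps$semidev_mgha, w))
  write_table(rbind(by_regime, all_row), config, "gap_summary.csv")
  invisible(NULL)
}

stage_project <- function(config) {
  profiles <- read_table(config, "profiles.csv")
  gaps <- read_table(config, "gaps.csv")
  demand <- project_countries(profiles, gaps,
                              horizon_years = config$spec$horizon_years)
  write_table(demand, config, "demand.csv")
  invisible(NULL)
}

stage_scenarios <- function(config) {
  gaps <- read_table(config, "gaps.csv")
  demand <- read_table(config, "demand.csv")
  grid <- run_scenario_grid(gaps, demand, config$f_values, config$rates,
                            config$spec, config$rest_production_mt,
                            config$rest_mode)
  write_table(grid, config, "scenarios.csv")
  combos <- expand.grid(yp_delta = config$deltas, area_delta = config$deltas,
                        KEEP.OUT.ATTRS = FALSE)
  sens <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    g <- climate_sensitivity(grid, combos$yp_delta[i], combos$area_delta[i])
    g$yp_delta <- combos$yp_delta[i]
    g$area_delta <- combos$area_delta[i]
    g
  }))
  write_table(sens, config, "sensitivity.csv")
  invisible(NULL)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the stages `synth` (generate weather, sites, profiles),
#' `simulate` (yield potential per country-regime), `gaps` (attainable
#' yields, exploitable gaps, area-weighted summaries, stability), `project`
#' (demand records and the 2050 projection), and `scenarios` (the
#' intensification x expansion grid plus climate sensitivity). Every stage
#' reads and writes CSV tables under `config$out_dir`; a failing stage aborts
#' with its name. A provenance manifest (`manifest.json`) records the full
#' configuration and an MD5 checksum of every output, so a rerun with the
#' same config can be verified byte-identical.
#'
#' @param config A [run_config()].
#' @param stages Subset of stages to run, in order.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "simulate", "gaps", "project",
                                    "scenarios")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(synth = stage_synth, simulate = stage_simulate,
                  gaps = stage_gaps, project = stage_project,
                  scenarios = stage_scenarios)
  for (st in stages) {
    message(sprintf("[ricegaps] stage '%s' (seed %d, %d countries, %d y)",
                    st, config$seed, config$n_countries, config$years))
    tryCatch(runners[[st]](config),
             error = function(e)
               stop(sprintf("stage '%s' failed: %s", st,
                            conditionMessage(e)), call. = FALSE))
  }
  files <- sort(list.files(config$out_dir, pattern = "\\.csv$"))
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  cfg_plain <- strip(config[setdiff(names(config), "out_dir")])
  manifest <- list(
    config = cfg_plain,
    stages = stages,
    files = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, pipeline_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate pipeline tables against schema and physical invariants
#'
#' Row-level checks: weather tables must have `tmax >= tmin`, `srad >= 0`,
#' `precip >= 0`, and contiguous daily dates; buffer tables positive areas
#' and a known water regime; profile tables non-negative masses and milling
#' rates within the typical 0.63-0.69 range.
#'
#' @param dir Directory holding pipeline CSV tables.
#' @return A data frame of violations (`table`, `row`, `rule`); zero rows for
#'   a valid set of tables.
#' @export
validate_tables <- function(dir) {
  viol <- list()
  note <- function(tbl, rows, rule) {
    if (length(rows))
      viol[[length(viol) + 1L]] <<- data.frame(table = tbl, row = rows,
                                               rule = rule)
  }
  for (f in list.files(dir, pattern = "^weather_.*\\.csv$")) {
    w <- tryCatch(read_weather_csv(file.path(dir, f)),
                  error = function(e) stop(sprintf("malformed CSV '%s': %s",
                                                   f, conditionMessage(e)),
                                           call. = FALSE))
    note(f, which(w$tmax < w$tmin), "tmax >= tmin")
    note(f, which(w$srad < 0), "srad >= 0")
    note(f, which(w$precip < 0), "precip >= 0")
    gaps <- which(diff(as.integer(w$date)) != 1L)
    note(f, gaps, "contiguous daily dates")
  }
  bpath <- file.path(dir, "buffers.csv")
  if (file.exists(bpath)) {
    b <- utils::read.csv(bpath, stringsAsFactors = FALSE)
    note("buffers.csv", which(b$area_ha <= 0), "area > 0")
    note("buffers.csv",
         which(!b$regime %in% c("irrigated", "rainfed_lowland",
                                "rainfed_upland")), "known water regime")
  }
  ppath <- file.path(dir, "profiles.csv")
  if (file.exists(ppath)) {
    p <- utils::read.csv(ppath, stringsAsFactors = FALSE)
    for (col in c("production_mt", "imports_mt", "exports_mt"))
      note("profiles.csv", which(p[[col]] < 0), paste(col, ">= 0"))
    note("profiles.csv",
         which(p$milling_rate < 0.63 | p$milling_rate > 0.69),
         "milling rate in [0.63, 0.69]")
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(table = character(), row = integer(), rule = character())
}
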