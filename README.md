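# ricegaps

Rice yield-gap analysis and 2050 self-sufficiency scenarios, as a tested,
fully offline R pipeline.

Africa produces roughly 60% of the rice it consumes; demand is projected to
more than double by 2050. Whether the continent can meet that demand without
a massive rise in imports or cropland conversion depends on how much of the
**exploitable yield gap** — the difference between an attainable yield ceiling
and what farmers currently harvest — can be closed on existing land.
`ricegaps` packages the quantitative chain needed to study that question at
desk scale, for crop modellers, agronomists, and food-policy analysts:

1. **Synthetic inputs** — a stochastic daily weather generator for monsoonal
   rice climates (sinusoidal temperature and clear-sky radiation, first-order
   Markov wet/dry occurrence with gamma rainfall depths, interannual monsoon
   variability), plus reference-buffer site networks and country profiles
   with the statistical structure the analysis assumes
   (`gen_weather()`, `gen_site_network()`, `qc_fill()`).
2. **Crop model** — a simplified daily rice-season simulator of yield
   potential *Yp* (irrigated) and water-limited yield potential *Yw*
   (rainfed lowland/upland): thermal-time phenology (base 14 °C, optimum
   30 °C, maximum 42 °C) with DRATE-style development-rate calibration by
   bisection; radiation-use-efficiency biomass accumulation
   (dB = RUE · 0.5 · Rs · f_int · T_ratio); a bunded soil-water bucket with
   groundwater capillary rise (shallow 40 cm / deep 100 cm scenarios blended
   50:50 for lowland rice); spikelet sterility above 35.6 °C; crop death
   after 3 consecutive days below 12 °C. Yields are paddy at 14% moisture
   (`simulate_season()`, `simulate_multi_year()`,
   `calibrate_development_rates()`).
3. **Upscaling** — greedy reference-buffer selection (≤ 20% overlap, ≥ 50%
   coverage target, > 5% climate-zone share), attainable yield = 0.8 · Yp
   (irrigated) or 0.7 · Yw (rainfed), exploitable gaps, area-weighted means,
   and inter-annual stability (CV and downside semi-deviation)
   (`select_reference_buffers()`, `attainable_yield()`, `exploitable_gap()`,
   `stability_metrics()`).
4. **Demand accounting** — baseline demand = production + imports − exports −
   stock change; milled→paddy conversion; 2050 demand = population ×
   per-capita demand; trend-extrapolated yields capped at attainable; SSR and
   deficit (`baseline_demand()`, `project_demand()`, `extrapolate_yield()`,
   `self_sufficiency_ratio()`).
5. **Scenarios** — a closure-fraction × area-expansion-rate grid (0.2 / 0.4 /
   0.6 M ha yr⁻¹ over 30 years) pooled continentally with a 1.05 demand
   multiplier, net imports priced at US$289 Mg⁻¹ paddy, land equivalents,
   required yield-gain rates, and −5% / −10% climate sensitivity
   (`run_scenario_grid()`, `continental_rollup()`, `climate_sensitivity()`).

`run_pipeline()` chains all stages reproducibly from one seed and writes
plain CSV tables plus a checksummed provenance manifest. A thin command-line
wrapper with `synth` / `simulate` / `gaps` / `project` / `scenarios` /
`run-all` subcommands lives at `inst/cli/ricegaps.R`.

## Worked example

Simulate 20 years of rainfed lowland rice at one synthetic monsoonal site,
then place a farmer yield of 2.8 Mg ha⁻¹ against the simulated ceiling:

```r
library(ricegaps)

w    <- gen_weather(weather_params(), years = 20, seed = 1)
cal  <- crop_calendar("transplanted", sowing_doy = 140,
                      transplanting_doy = 158, maturity_doy = 262)
phen <- calibrate_development_rates(w, cal)

series <- simulate_multi_year(w, cal, "rainfed_lowland", phen = phen)
yw <- annual_yield(series)          # 50:50 shallow/deep groundwater blend

mean(yw)                            # 9.86  Mg/ha water-limited potential
stability_metrics(yw)$cv            # 3.9   % inter-annual CV
att <- attainable_yield(mean(yw), "rainfed_lowland")   # 6.90 Mg/ha
exploitable_gap(att, ya = 2.8)      # gap 4.10 Mg/ha = 59% of attainable
required_gain_rate(2.8, att, f = 1, horizon_years = 30) # 137 kg/ha/yr
```

Reading: the site could attain 6.9 Mg ha⁻¹ (70% of its 9.9 Mg ha⁻¹
water-limited potential); at 2.8 Mg ha⁻¹ actual yield the exploitable gap is
59% of attainable, and closing it fully by 2050 would take a sustained gain
of 137 kg ha⁻¹ yr⁻¹ — well above historically observed rates, which is why
half-closure scenarios are the realistic benchmark.

The full pipeline on a synthetic 15-country continent:

```r
cfg <- run_config(out_dir = "out", seed = 1)
run_pipeline(cfg)   # writes gaps.csv, demand.csv, scenarios.csv, manifest.json, ...
```

## Scope

The package deliberately does not re-implement a full crop model (no
nutrient, pest, or disease simulation), GIS/raster processing, climate-zone
derivation, population projection, or equilibrium trade modelling; those
enter as inputs or fixed parameters. See the methods vignette
(`vignettes/methods.Rmd`) for the model equations, parameter choices, and
known limitations.
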