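---
title: "Models and methods in ricegaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ricegaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ricegaps` chains five stages — synthetic inputs, a daily crop-season
simulator, yield-gap upscaling, demand accounting, and a 2050 scenario grid.
This vignette documents the models, the parameters that matter, the numerical
choices, and what the package's passing tests do and do not establish.

## 1. The weather generator

Rainfed rice yields are set by when the monsoon arrives, how long it lasts,
and how rain is spaced within it. The generator therefore has three layers:

* **Annual cycles.** Daily mean temperature and clear-sky solar radiation
  follow a sinusoid peaking mid-monsoon. Defaults describe a warm monsoonal
  rice climate: mean 26&nbsp;°C with ±3&nbsp;°C seasonal amplitude and a
  9&nbsp;°C diurnal range; clear-sky radiation 18 ± 4&nbsp;MJ&nbsp;m⁻²&nbsp;d⁻¹.
* **Rainfall occurrence.** A two-state (wet/dry) **first-order Markov chain**
  with P(wet | wet) = 0.78 and the dry-to-wet probability derived so that the
  configured marginal wet-day probability (0.55 in the monsoon, 0.05 outside)
  is preserved. We chose a Markov chain over independent Bernoulli draws
  because spell persistence is what produces multi-day dry spells; without
  it the soil bucket never empties mid-season and rainfed crops are
  effectively never droughted, which contradicts the behaviour of real
  rainfed systems. First-order occurrence chains are the standard in daily
  weather generators of the Richardson type.
* **Interannual structure.** Monsoon onset (mean day 150, sd 12&nbsp;d),
  length (110 ± 15&nbsp;d), and a multiplicative wetness factor
  (sd 0.25) vary by year. Good and bad monsoon years, not daily noise, are
  what drive year-to-year yield variability. Wet-day depths are gamma
  distributed (mean 11&nbsp;mm, shape 0.75: many small events, occasional
  downpours; annual total ≈ 800&nbsp;mm, a Sudanian-savanna rice climate).
  Radiation on wet days is attenuated by the factor 0.78; deeper attenuation
  makes failed-monsoon years implausibly sunny and overstates the negative
  rain–radiation correlation.

The generator is a pure function of its parameters and seed (the caller's RNG
state is saved and restored), includes leap days, and guarantees
`tmax ≥ tmin`, `srad ≥ 0`, `precip ≥ 0`. `qc_fill()` performs the standard
station quality-control step — linear interpolation across gaps
(`stats::approx`), nearest-value fill at series boundaries (with a warning),
idempotent by construction.

**What it does not emulate:** spatial correlation between sites, humidity and
wind (hence the radiation-based reference ET below), temperature–rainfall
feedbacks beyond the wet-day attenuation, and climate trends. Passing tests
on generated weather therefore say nothing about skill against observed
station records; they establish that the analysis chain behaves correctly on
inputs with the assumed statistical structure.

## 2. The crop-season simulator

A deliberately small daily model rather than a full crop simulator: the goal
is to honour every stated parameter of the study design while remaining
auditable in a few hundred lines.

**Phenology.** Development stage DVS runs 0 → 1 (flowering) → 2 (maturity)
through four stages with constant rates (juvenile to DVS 0.4, photoperiod
stage to 0.65, panicle development to 1.0, reproductive to 2.0). Daily
thermal time is piecewise linear in mean temperature: zero at or below the
14&nbsp;°C base, rising to 16&nbsp;°C·d at the 30&nbsp;°C optimum, declining
to zero at 42&nbsp;°C. The paper's design states only the base; optimum and
maximum follow rice-model convention and are configurable. Photoperiod
sensitivity is off (10&nbsp;h optimum never binds), so constant per-stage
rates make DVS a piecewise-linear function of *cumulative* thermal time —
phenology reduces to thresholds on one cumulative sum, which is both exact
and fast.

**Calibration** (`calibrate_development_rates()`) is DRATE-style: bisection
on a single multiplier of the three pre-flowering rates until the mean
simulated flowering date across all weather years matches the calendar to
±1&nbsp;day, then bisection on the reproductive rate for maturity. Flowering
defaults to maturity − 30&nbsp;d when only maturity is known. Sowing dates
whose cycle cannot be observed within the series (closer than the target
cycle length + 30&nbsp;d to the series end) are excluded from the calibration
mean. Bisection runs on a log scale over [10⁻², 10²] (multiplier) and
[10⁻⁵, 1] (reproductive rate); a target unreachable at the bounds raises a
calibration-infeasible error rather than returning a bad fit.

**Canopy and growth.** Leaf-area index is prescribed: linear from 0 to 6 at
flowering, declining to 2 at maturity; interception
f_int = 1 − exp(−0.5·LAI). Daily biomass is
RUE · 0.5 · Rs · f_int · T_ratio with RUE = 2.2&nbsp;g&nbsp;MJ⁻¹(PAR)
and the photosynthetically active fraction fixed at 0.5. For transplanted
rice, canopy growth in the main field starts at transplanting (phenology runs
from sowing); transplanting shock is ignored. Grain =
HI·B·(1 − sterility) + 0.2 · (stem biomass at flowering), with HI = 0.45,
stem share 0.4 of biomass at flowering, capped at a 0.55 harvest-index
ceiling on dry matter; yields are reported as paddy at 14% moisture
(dry grain / 0.86). These canopy defaults were chosen once to place
simulated potentials in the realistic 4–11&nbsp;Mg&nbsp;ha⁻¹ range across the
generator's climate span; absolute yields are *not* calibrated to any
published site value, so tests assert orderings and invariants, not absolute
levels.

**Temperature stress.** Spikelet sterility rises 0.10 per °C of daily maximum
above 35.6&nbsp;°C, averaged over the flowering window (DVS 0.96–1.2,
clamped to [0, 1]). The crop dies — yield zero — after 3 consecutive days
with mean temperature below 12&nbsp;°C. Cold sterility is omitted: only the
lethal rule is numerically specified in the study design.

**Soil water.** A single rooted bucket plus, for lowland rice, a ponded layer
held by a 25&nbsp;cm bund. Stated profile constants: lowland
θ_init/θ_sat/K_sat = 0.57/0.56&nbsp;m³&nbsp;m⁻³/10.79&nbsp;cm&nbsp;d⁻¹ (rooting
depth 40&nbsp;cm), upland 0.39/0.38/99.77 (60&nbsp;cm, no bund, groundwater
at 1000&nbsp;cm). Two parameters close the bucket and are our own choice:
field capacity (0.42 lowland — clay loam, plant-available water
≈ 0.17&nbsp;m³&nbsp;m⁻³; 0.15 upland — sandy loam, ≈ 0.08) and wilting point
(0.25 / 0.07). Without free drainage above field capacity, a sandy upland
profile would paradoxically store more plant-available water than a clayey
lowland one. The daily step is, in order: inflow (rain + capillary rise)
fills the root zone to saturation; excess ponds to the bund height, the rest
runs off; transpiration is met from pond then root-zone water above wilting
point (the **transpiration ratio** = supplied/demanded scales that day's
growth); bare-soil/pond evaporation (0.6·(1 − f_int)·ET₀) is drawn next;
drainage removes water above field capacity and then ponded water, jointly
capped at K_sat per day. The balance closes exactly —
Δ(storage + pond) = inflow − runoff − ET − evaporation − drainage — and the
test suite audits this to machine precision. Each state update is monotone
in water input, which yields the groundwater (40 ≥ 100 ≥ 1000&nbsp;cm) and
rainfall-scaling monotonicity properties as theorems of the scheme, verified
by test.

Reference ET is a Hargreaves-type form driven by measured radiation,
ET₀ = 0.0135·(T + 17.8)·Rs/2.45&nbsp;mm, because the generator provides no
humidity or wind; crop demand is k_c·f_int·ET₀ with k_c = 1.15. Capillary
rise is linear in water-table depth — 5&nbsp;mm&nbsp;d⁻¹ at 40&nbsp;cm,
1&nbsp;mm&nbsp;d⁻¹ at 100&nbsp;cm, zero from 200&nbsp;cm — a transparent rule
that preserves the shallow ≥ deep ordering the analysis relies on. Rainfed
lowland rice is simulated under both water-table scenarios and their 50:50
area-weighted blend is the regime's representative series.

## 3. Upscaling

Reference-buffer selection is greedy: restrict to climate zones holding more
than 5% of the regime's national area, sort by harvested area (ties broken
by id for determinism), accept unless overlap with an accepted buffer
exceeds 20%, stop at 50% cumulative coverage. A shortfall is a warning, not
an error — partial coverage with climate-zone extrapolation is standard
practice. Attainable yield is 0.8·Yp (irrigated) or 0.7·Yw (rainfed); the
exploitable gap is attainable − actual, retained when negative (gap closed)
for reporting but contributing zero headroom to intensification scenarios.
All aggregation is by harvested-area weighting. Stability uses the sample
CV (100·sd/mean) and the downside semi-deviation
√(mean(min(0, xᵢ − benchmark)²)); the benchmark defaults to the series mean,
the usual convention when no target return is specified, and is
configurable.

## 4. Demand accounting and projection

Baseline demand is the accounting identity production + imports − exports −
stock change, with positive stock change meaning stocks were built up (grain
withheld from consumption) and therefore subtracted — the identity's usual
sign convention. Per-capita quantities reported on a milled basis are
converted to paddy by dividing by the milling rate (typically 0.63–0.69;
values outside draw a warning). 2050 demand is population × per-capita
demand (kg → Mt via 10⁻⁹), both paddy basis. Yield extrapolation continues
the historical linear trend, capped at the attainable yield; a cap already
below the current yield returns the current yield with a warning. SSR is
production/demand; the deficit is demand − production (negative = exportable
surplus). Both identities hold exactly and are asserted as such.

## 5. The scenario grid

Each cell of the closure-fraction × expansion-rate grid is one continental
roll-up. Intensified yield is ya + f·max(0, attainable − ya). Expansion
(0.2 / 0.4 / 0.6&nbsp;M&nbsp;ha&nbsp;yr⁻¹ × 30&nbsp;y) is allocated pro rata
to current harvested area across countries and regimes — i.e. uniform area
scaling — since total rates are fixed but their allocation is not; regime
shares within countries are thereby preserved, matching the no-change
assumption on the irrigated fraction. Demand interpolates linearly between
the baseline and the 2050 projection across the 30-year span (so a 0-year
horizon reproduces the baseline SSR identically) and is multiplied by 1.05
continentally to cover countries without demand projections. Countries pool:
surpluses offset deficits before imports are computed. Net imports are
priced at a constant US$289&nbsp;Mg⁻¹ paddy (2018–2020 average); no price
response is modelled. Production for producing countries outside the study
set scales their baseline by the study-average *relative yield increase*
(area-weighted intensified over current yield); a production-ratio mode
(including expansion) and a no-change mode are available, since the
published wording admits several readings. Climate sensitivity rescales
attainable yields by 1 + δ_yp *before* gap closure and the expansion rate by
1 + δ_area, then recomputes the grid.

Internal reporting keeps full precision; rounding happens only in displays.

## 6. Numerical choices and degenerate inputs

* Calibration tolerance ±1 day on the mean date; bisection 60 iterations,
  geometric midpoint.
* Zero radiation gives zero biomass and yield; an all-base-temperature
  series never advances DVS and raises a cycle-incomplete error, as does a
  series that ends before maturity.
* Empty sterility windows score 0; CV is an error on zero-mean series;
  all-zero weights are an error in weighted means.
* The pipeline writes UTF-8 CSVs with unit-suffixed column names (`_mgha`,
  `_mha`, `_mt`, `_usd_b`) and a manifest with MD5 checksums; a rerun from
  the same config is byte-identical, which the suite asserts.

## 7. Problem sizes used in the tests

The test suite runs on 4–20-year weather series, networks of 2–20 countries,
and a fine (Δf = 0.01) one-rate scenario grid; the acceptance script uses a
15-country, 20-year network — the study-scale layout (≈ 15&nbsp;M&nbsp;ha of
rice across ~30 strata). These sizes give stable aggregates while keeping a
full run to seconds.

## 8. Known limitations

* Absolute simulated yields depend on the RUE/LAI/HI defaults; only
  orderings, invariants, and published worked-example arithmetic are
  asserted. Cross-validation against field-trial yields is out of scope.
* The stability ordering irrigated < rainfed lowland < rainfed upland holds
  on the tested configuration, but the irrigated-vs-lowland leg is marginal:
  the shallow-groundwater half of the lowland blend is nearly unstressed by
  construction, and dry years are also sunny years, which partially offsets
  drought losses. The robust, seed-independent statement is that upland is
  far less stable than either. The upland >> lowland gap is typically an
  order of magnitude in CV; irrigated-vs-lowland differences are fractions
  of a percentage point either way.
* One cycle per year is generated by default; the multi-cycle interface
  (list of calendars) exists but double-cropping calendars are not part of
  the default network.
* No nutrient, pest, weed, or disease limitation; no transpirational
  cooling of the canopy during flowering; no hourly microclimate.
* Scenario economics are accounting, not equilibrium: constant price, no
  supply or demand response, frictionless continental trade.
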