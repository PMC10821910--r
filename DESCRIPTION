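Package: ricegaps
Title: Rice Yield Gaps and 2050 Self-Sufficiency Scenarios for Africa
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for rice yield-gap analysis and food
    self-sufficiency scenario assessment. Includes a stochastic daily weather
    generator for monsoonal rice environments, a simplified ORYZA-style
    crop-season simulator for yield potential under irrigated, rainfed lowland,
    and rainfed upland water regimes (thermal-time phenology with development-
    rate calibration, radiation-use-efficiency biomass accumulation, a bunded
    soil water bucket with groundwater capillary rise, heat-induced spikelet
    sterility, and a cold-death rule), GYGA-style reference-buffer selection
    and area-weighted upscaling of exploitable yield gaps, country-level rice
    demand accounting and 2050 projection, and an intensification-by-area-
    expansion scenario grid with import cost and climate sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
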