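#' Soil profile for the water-balance bucket
#'
#' Describes a rooted soil bucket plus (for lowland rice) a ponded layer held
#' by a bund. Defaults follow the two canonical rainfed rice profiles: a
#' non-puddled clayey loam with a 25 cm bund for lowland rice
#' (theta_init/theta_sat/ksat = 0.57 / 0.56 m3 m-3 / 10.79 cm d-1) and a
#' non-puddled sandy loam without a bund for upland rice
#' (0.39 / 0.38 m3 m-3 / 99.77 cm d-1, groundwater at 1000 cm). Field capacity
#' and wilting point close the bucket: water above field capacity drains
#' freely (capped at `ksat` per day) and water below wilting point is
#' unavailable to the crop.
#'
#' @param environment `"lowland"` or `"upland"`.
#' @param groundwater_cm Groundwater table depth, cm (lowland scenarios use 40
#'   and 100 cm; upland uses 1000 cm).
#' @param bund_cm Bund height, cm (25 lowland, 0 upland).
#' @param theta_init,theta_sat,theta_fc,theta_wp Initial, saturated, field-
#'   capacity, and wilting-point volumetric water contents, m3 m-3
#'   (`theta_init <= theta_sat + 0.02` tolerated, excess capped at saturation).
#' @param ksat_cmd Saturated hydraulic conductivity, cm d-1.
#' @param root_depth_cm Rooting depth, cm.
#' @return An object of class `soil_profile` with derived storages in mm.
#' @export
soil_profile <- function(environment = c("lowland", "upland"),
                         groundwater_cm = NULL, bund_cm = NULL,
                         theta_init = NULL, theta_sat = NULL,
                         theta_fc = NULL, theta_wp = NULL,
                         ksat_cmd = NULL, root_depth_cm = NULL) {
  environment <- match.arg(environment)
  def <- if (environment == "lowland") {
    list(groundwater_cm = 40, bund_cm = 25, theta_init = 0.57,
         theta_sat = 0.56, theta_fc = 0.42, theta_wp = 0.25,
         ksat_cmd = 10.79, root_depth_cm = 40)
  } else {
    list(groundwater_cm = 1000, bund_cm = 0, theta_init = 0.39,
         theta_sat = 0.38, theta_fc = 0.15, theta_wp = 0.07,
         ksat_cmd = 99.77, root_depth_cm = 60)
  }
  given <- list(groundwater_cm = groundwater_cm, bund_cm = bund_cm,
                theta_init = theta_init, theta_sat = theta_sat,
                theta_fc = theta_fc, theta_wp = theta_wp,
                ksat_cmd = ksat_cmd, root_depth_cm = root_depth_cm)
  for (nm in names(given)) if (!is.null(given[[nm]])) def[[nm]] <- given[[nm]]
  if (def$theta_init > def$theta_sat + 0.02)
    stop("theta_init must be <= theta_sat + 0.02", call. = FALSE)
  if (!(def$theta_wp < def$theta_fc && def$theta_fc <= def$theta_sat))
    stop("need theta_wp < theta_fc <= theta_sat", call. = FALSE)
  stopifnot(def$ksat_cmd > 0, def$root_depth_cm > 0, def$groundwater_cm > 0,
            def$bund_cm >= 0)
  depth_mm <- def$root_depth_cm * 10
  structure(c(def, list(environment = environment,
                        s_max = def$theta_sat * depth_mm,
                        s_fc = def$theta_fc * depth_mm,
                        s_wp = def$theta_wp * depth_mm,
                        s_init = min(def$theta_init, def$theta_sat) * depth_mm,
                        bund_mm = def$bund_cm * 10,
                        ksat_mm = def$ksat_cmd * 10)),
            class = "soil_profile")
}

#' Capillary rise from the groundwater table
#'
#' Linear in groundwater depth: 5 mm d-1 at 40 cm (or shallower), declining to
#' 1 mm d-1 at 100 cm and to zero at 200 cm or deeper. This preserves the
#' shallow >= deep ordering of water-limited yields while keeping the highly
#' site-specific groundwater contribution to a single transparent rule.
#'
#' @param groundwater_cm Groundwater depth, cm; vectorised.
#' @return Capillary-rise flux, mm d-1.
#' @export
capillary_rise <- function(groundwater_cm) {
  ifelse(groundwater_cm <= 40, 5,
         ifelse(groundwater_cm <= 100,
                5 - 4 * (groundwater_cm - 40) / 60,
                ifelse(groundwater_cm < 200,
                       1 - (groundwater_cm - 100) / 100, 0)))
}

#' Initial soil-water state
#'
#' @param soil A [soil_profile()].
#' @return List with root-zone storage `s` and ponded depth `pond` (mm).
#' @export
soil_water_init <- function(soil) {
  stopifnot(inherits(soil, "soil_profile"))
  list(s = soil$s_init, pond = 0)
}

#' One daily step of the soil water balance
#'
#' Bucket update, in order: inflow (rain + irrigation + capillary rise) fills
#' the root zone to saturation, the excess ponds up to the bund height and the
#' remainder runs off; crop transpiration is met first from the pond and then
#' from root-zone water above wilting point; bare-soil/pond evaporation is
#' taken next from the same stores; finally, water above field capacity and
#' then ponded water drain downward, jointly capped at `ksat` per day. The
#' mass balance closes exactly:
#' `delta(s + pond) = inflow - runoff - et - evap - drainage`.
#'
#' @param state State list from [soil_water_init()] or a previous step.
#' @param rain,irrigation,et_demand,capillary Daily fluxes, mm (all >= 0).
#' @param evap_demand Bare-soil/pond evaporative demand, mm (>= 0); does not
#'   enter the transpiration ratio.
#' @param soil A [soil_profile()].
#' @return List with `state` (updated), `ratio` (transpiration ratio = actual /
#'   demanded transpiration, in \[0, 1\]; 1 when demand is zero), and `fluxes`
#'   (`inflow`, `runoff`, `et`, `evap`, `drainage`, all mm).
#' @export
soil_water_step <- function(state, rain, irrigation = 0, et_demand = 0,
                            capillary = 0, evap_demand = 0, soil) {
  if (min(rain, irrigation, et_demand, capillary, evap_demand) < 0)
    stop("all fluxes must be >= 0", call. = FALSE)
  s <- state$s; pond <- state$pond
  inflow <- rain + irrigation + capillary
  ds <- min(soil$s_max - s, inflow)
  s <- s + ds
  pond <- pond + inflow - ds
  runoff <- max(0, pond - soil$bund_mm)
  pond <- pond - runoff
  if (et_demand > 0) {
    t1 <- min(pond, et_demand)
    pond <- pond - t1
    t2 <- min(max(0, s - soil$s_wp), et_demand - t1)
    s <- s - t2
    et <- t1 + t2
    ratio <- et / et_demand
  } else {
    et <- 0
    ratio <- 1
  }
  e1 <- min(pond, evap_demand)
  pond <- pond - e1
  e2 <- min(max(0, s - soil$s_wp), evap_demand - e1)
  s <- s - e2
  free <- soil$ksat_mm
  dr1 <- min(free, max(0, s - soil$s_fc))
  s <- s - dr1
  dr2 <- min(free - dr1, pond)
  pond <- pond - dr2
  list(state = list(s = s, pond = pond), ratio = ratio,
       fluxes = list(inflow = inflow, runoff = runoff, et = et, evap = e1 + e2,
                     drainage = dr1 + dr2))
}
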