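#' Greedy selection of reference buffers
#'
#' GYGA-style site selection for one country x water regime: candidates are
#' restricted to climate zones holding more than `cz_min_share` of the
#' national harvested area for the regime, then taken greedily by descending
#' harvested area, discarding any buffer that overlaps an already selected
#' buffer by more than `max_overlap`, until cumulative coverage of the
#' national area reaches `target_coverage` (or candidates run out, in which
#' case the shortfall is reported as a warning -- partial coverage with
#' climate-zone extrapolation is acceptable in practice).
#'
#' @param candidates Data frame with columns `id`, `climate_zone`, `area_ha`.
#' @param overlaps Data frame of pairwise overlap fractions with columns
#'   `id_a`, `id_b`, `fraction` (symmetric; missing pairs mean zero overlap),
#'   or `NULL` for no overlaps.
#' @param national_area_ha National harvested area for the regime, ha (> 0).
#' @param cz_min_share Minimum climate-zone share of national area (0.05).
#' @param max_overlap Maximum tolerated overlap with selected buffers (0.20).
#' @param target_coverage Coverage at which selection stops (0.50).
#' @return The selected subset of `candidates`, in selection order, with a
#'   `coverage` attribute (selected area / national area).
#' @export
select_reference_buffers <- function(candidates, overlaps = NULL,
                                     national_area_ha,
                                     cz_min_share = 0.05, max_overlap = 0.20,
                                     target_coverage = 0.50) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("empty candidate list", call. = FALSE)
  stopifnot(all(c("id", "climate_zone", "area_ha") %in% names(candidates)),
            national_area_ha > 0, all(candidates$area_ha > 0))
  cz_area <- tapply(candidates$area_ha, candidates$climate_zone, sum)
  keep_cz <- names(cz_area)[cz_area / national_area_ha > cz_min_share]
  cand <- candidates[candidates$climate_zone %in% keep_cz, ]
  if (nrow(cand) == 0L)
    stop("no candidate climate zone holds more than the minimum area share",
         call. = FALSE)
  cand <- cand[order(-cand$area_ha, cand$id), ]

  overlap_of <- function(a, b) {
    if (is.null(overlaps) || nrow(overlaps) == 0L) return(0)
    hit <- (overlaps$id_a == a & overlaps$id_b == b) |
      (overlaps$id_a == b & overlaps$id_b == a)
    if (any(hit)) max(overlaps$fraction[hit]) else 0
  }

  selected <- integer(0)
  coverage <- 0
  for (i in seq_len(nrow(cand))) {
    if (coverage >= target_coverage) break
    ok <- all(vapply(selected,
                     function(j) overlap_of(cand$id[i], cand$id[j]) <= max_overlap,
                     logical(1)))
    if (ok) {
      selected <- c(selected, i)
      coverage <- coverage + cand$area_ha[i] / national_area_ha
    }
  }
  if (coverage < target_coverage)
    warning(sprintf("coverage shortfall: selected buffers cover %.0f%% (< %.0f%%) of national area",
                    100 * coverage, 100 * target_coverage), call. = FALSE)
  out <- cand[selected, ]
  attr(out, "coverage") <- coverage
  out
}

#' Attainable yield from (water-limited) yield potential
#'
#' The realistic farmer ceiling: 80% of yield potential for irrigated rice and
#' 70% of water-limited yield potential for rainfed rice.
#'
#' @param y Simulated (water-limited) yield potential, Mg ha-1 (>= 0);
#'   vectorised with `regime`.
#' @param regime `"irrigated"`, `"rainfed_lowland"`, or `"rainfed_upland"`.
#' @return Attainable yield, Mg ha-1.
#' @examples
#' attainable_yield(10, "irrigated")        # 8.0
#' attainable_yield(7, "rainfed_lowland")   # 4.9
#' @export
attainable_yield <- function(y, regime) {
  if (any(y < 0)) stop("yield must be >= 0", call. = FALSE)
  ok <- regime %in% c("irrigated", "rainfed_lowland", "rainfed_upland")
  if (!all(ok)) stop(sprintf("unknown regime: %s",
                             paste(unique(regime[!ok]), collapse = ", ")),
                     call. = FALSE)
  y * ifelse(regime == "irrigated", 0.8, 0.7)
}

#' Exploitable yield gap
#'
#' Difference between the attainable yield and the actual farmers' yield.
#' Negative gaps (farmers at or above the attainable level, as in the most
#' intensive irrigated systems) are retained and flagged as closed rather than
#' floored at zero.
#'
#' @param attainable Attainable yield, Mg ha-1 (> 0); vectorised.
#' @param ya Actual farmers' yield, Mg ha-1.
#' @return A data frame with `gap` (Mg ha-1), `gap_fraction` (gap /
#'   attainable), and `closed` (logical, `gap <= 0`).
#' @export
exploitable_gap <- function(attainable, ya) {
  if (any(attainable <= 0)) stop("attainable must be > 0", call. = FALSE)
  gap <- attainable - ya
  data.frame(gap = gap, gap_fraction = gap / attainable, closed = gap <= 0)
}

#' Area-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Harvested areas (same length, sum > 0, none negative).
#' @return `sum(values * weights) / sum(weights)`.
#' @export
area_weighted_mean <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights must have the same length", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  sum(values * weights) / sum(weights)
}

#' Inter-annual yield stability metrics
#'
#' Coefficient of variation (sample standard deviation over mean, in percent)
#' and downside semi-deviation: the root mean square of below-benchmark
#' deviations, with the series mean as the default benchmark. A constant
#' series scores zero on both.
#'
#' @param series Numeric yield series, Mg ha-1 (length >= 2).
#' @param benchmark Downside-risk benchmark; defaults to the series mean.
#' @return List with `cv` (percent) and `semidev` (Mg ha-1).
#' @examples
#' stability_metrics(c(4, 6))  # cv ~ 28.3%, semidev ~ 0.707
#' @export
stability_metrics <- function(series, benchmark = mean(series)) {
  if (length(series) < 2L) stop("need at least 2 years", call. = FALSE)
  m <- mean(series)
  if (m == 0) stop("cv undefined for a zero-mean series", call. = FALSE)
  list(cv = 100 * stats::sd(series) / m,
       semidev = sqrt(mean(pmin(0, series - benchmark)^2)))
}
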