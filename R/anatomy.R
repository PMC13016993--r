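# Stomatal anatomical trait derivation from leaf-impression measurements.
#
# Grass stomata are approximated as rectangles: stomatal size is
# SL x SCW (complex length x complex width) and maximum pore area is
# PL x GCW (pore length x guard-cell width). Anatomical maximum stomatal
# conductance uses a diffusion equation with one-end correction, with pore
# depth taken as half the guard-cell width.

#' Physical constants for anatomical conductance
#'
#' @param d diffusivity of water vapor in air, m^2 s^-1.
#' @param v molar volume of air at 25 deg C, m^3 mol^-1.
#' @param fov_area area of one microscope field of view, mm^2.
#' @param pi_value value used for pi; set `3.1415` to reproduce computations
#'   done with the truncated constant.
#' @return list of constants used by [gsw_max_anatomical()].
#' @export
stomatal_constants <- function(d = 2.49e-5, v = 0.0245, fov_area = 0.59,
                               pi_value = pi) {
  stopifnot(d > 0, v > 0, fov_area > 0, pi_value > 3, pi_value < 3.2)
  list(d = d, v = v, fov_area = fov_area, pi_value = pi_value)
}

#' Stomatal density from field-of-view counts
#'
#' @param counts integer vector of stomatal counts, one per field of view.
#' @param fov_area field-of-view area in mm^2 (default 0.59).
#' @return density in stomata mm^-2: `mean(counts) / fov_area`.
#' @export
stomatal_density <- function(counts, fov_area = 0.59) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (fov_area <= 0) stop("fov_area must be positive")
  mean(counts) / fov_area
}

#' Stomatal size and maximum pore area (rectangular approximation)
#'
#' Per-stoma products are averaged (not means multiplied): with several
#' stomata scored per impression, the mean of products is the unbiased
#' estimator of mean area. `mean_of_products = FALSE` switches to the
#' product-of-means order.
#'
#' @param SL,SCW stomatal complex length and width, um (vectors over stomata).
#' @param mean_of_products average per-stoma products (default) or multiply
#'   the two trait means.
#' @return area in um^2.
#' @export
stomatal_size <- function(SL, SCW, mean_of_products = TRUE) {
  if (length(SL) != length(SCW)) stop("SL and SCW must have equal length")
  if (any(SL <= 0) || any(SCW <= 0)) stop("dimensions must be positive")
  if (mean_of_products) mean(SL * SCW) else mean(SL) * mean(SCW)
}

#' @rdname stomatal_size
#' @param PL,GCW pore length and guard-cell width, um.
#' @export
max_pore_area <- function(PL, GCW, mean_of_products = TRUE) {
  if (length(PL) != length(GCW)) stop("PL and GCW must have equal length")
  if (any(PL <= 0) || any(GCW <= 0)) stop("dimensions must be positive")
  if (mean_of_products) mean(PL * GCW) else mean(PL) * mean(GCW)
}

#' Stomatal pore area per leaf area
#'
#' @param PAmax maximum pore area, um^2.
#' @param SD stomatal density, mm^-2.
#' @return SPALA in um^2 mm^-2: `PAmax * SD`.
#' @export
spala <- function(PAmax, SD) {
  if (any(PAmax < 0) || any(SD < 0)) stop("inputs must be non-negative")
  PAmax * SD
}

#' Anatomical maximum stomatal conductance to water vapor
#'
#' One-end-corrected diffusion form
#' \deqn{g = \frac{d \cdot SD \cdot PA_{max}}
#'   {v \, (l + \frac{\pi}{2}\sqrt{PA_{max}/\pi})}}
#' with pore depth \eqn{l = GCW/2}. Inputs are in field units (mm^-2, um,
#' um^2) and converted to SI internally; the result is mol m^-2 s^-1.
#'
#' @param SD stomatal density, mm^-2.
#' @param PAmax maximum pore area, um^2.
#' @param GCW guard-cell width, um (pore depth is GCW/2).
#' @param constants from [stomatal_constants()].
#' @return conductance in mol m^-2 s^-1 (vectorized over inputs).
#' @export
gsw_max_anatomical <- function(SD, PAmax, GCW,
                               constants = stomatal_constants()) {
  if (any(SD <= 0) || any(PAmax <= 0) || any(GCW <= 0))
    stop("SD, PAmax and GCW must be positive")
  sd_si <- SD * 1e6          # mm^-2 -> m^-2
  pa_si <- PAmax * 1e-12     # um^2  -> m^2
  l_si <- (GCW / 2) * 1e-6   # um    -> m
  p <- constants$pi_value
  num <- constants$d * sd_si * pa_si
  den <- constants$v * (l_si + (p / 2) * sqrt(pa_si / p))
  num / den
}

#' Derive per-surface traits from one impression record
#'
#' An impression record holds, for one plant and one leaf surface, the
#' field-of-view stomatal counts and per-stoma dimension measurements.
#'
#' @param record list (or one-row data.frame of list-columns) with elements
#'   `counts`, `SL`, `SCW`, `PL`, `GCW` and optionally `fov_area`.
#' @param constants from [stomatal_constants()].
#' @param mean_of_products see [stomatal_size()].
#' @return named list: `SD`, `SS`, `PAmax`, `SPALA`, `gsw_max`.
#' @export
derive_surface_traits <- function(record, constants = stomatal_constants(),
                                  mean_of_products = TRUE) {
  fov <- if (!is.null(record$fov_area)) record$fov_area else constants$fov_area
  if (any(record$PL > record$SL)) stop("PL must not exceed SL")
  if (any(record$GCW > record$SCW)) stop("GCW must not exceed SCW")
  SD <- stomatal_density(record$counts, fov)
  SS <- stomatal_size(record$SL, record$SCW, mean_of_products)
  PAmax <- max_pore_area(record$PL, record$GCW, mean_of_products)
  g <- if (SD > 0) gsw_max_anatomical(SD, PAmax, mean(record$GCW), constants) else 0
  list(SD = SD, SS = SS, PAmax = PAmax, SPALA = spala(PAmax, SD), gsw_max = g)
}

#' Combine adaxial and abaxial surface traits into whole-leaf aggregates
#'
#' Density-like quantities (SD, SPALA, anatomical conductance) sum over
#' surfaces; size-like quantities (SS, PAmax) average. Both surfaces are
#' required: there is no silent single-surface fallback.
#'
#' @param adaxial,abaxial per-surface trait lists from
#'   [derive_surface_traits()].
#' @return named list: `SD_total`, `SPALA_total`, `g_total`, `SS_mean`,
#'   `PAmax_mean`.
#' @export
combine_surfaces <- function(adaxial, abaxial) {
  if (is.null(adaxial) || is.null(abaxial))
    stop("both adaxial and abaxial surface traits are required")
  need <- c("SD", "SS", "PAmax", "SPALA", "gsw_max")
  if (!all(need %in% names(adaxial)) || !all(need %in% names(abaxial)))
    stop("surface trait lists must contain: ", paste(need, collapse = ", "))
  list(SD_total = adaxial$SD + abaxial$SD,
       SPALA_total = adaxial$SPALA + abaxial$SPALA,
       g_total = adaxial$gsw_max + abaxial$gsw_max,
       SS_mean = (adaxial$SS + abaxial$SS) / 2,
       PAmax_mean = (adaxial$PAmax + abaxial$PAmax) / 2)
}

#' Derive anatomical traits for a table of impression records
#'
#' @param impressions data.frame with columns `plant_id`, `surface`
#'   (`"adaxial"`/`"abaxial"`) and list-columns `counts`, `SL`, `SCW`,
#'   `PL`, `GCW` (as produced by [simulate_impressions()]).
#' @param constants from [stomatal_constants()].
#' @param mean_of_products see [stomatal_size()].
#' @return data.frame, one row per plant: per-surface traits (suffixes
#'   `_ad`, `_ab`) plus the whole-leaf aggregates.
#' @export
derive_anatomy <- function(impressions, constants = stomatal_constants(),
                           mean_of_products = TRUE) {
  stopifnot(all(c("plant_id", "surface") %in% names(impressions)))
  plants <- unique(impressions$plant_id)
  rows <- lapply(plants, function(p) {
    sub <- impressions[impressions$plant_id == p, , drop = FALSE]
    one <- function(surf) {
      i <- which(sub$surface == surf)
      if (length(i) != 1)
        stop("plant ", p, " must have exactly one ", surf, " record")
      rec <- list(counts = sub$counts[[i]], SL = sub$SL[[i]], SCW = sub$SCW[[i]],
                  PL = sub$PL[[i]], GCW = sub$GCW[[i]],
                  fov_area = if ("fov_area" %in% names(sub)) sub$fov_area[i] else NULL)
      derive_surface_traits(rec, constants, mean_of_products)
    }
    ad <- one("adaxial"); ab <- one("abaxial")
    tot <- combine_surfaces(ad, ab)
    data.frame(plant_id = p,
               SD_ad = ad$SD, SD_ab = ab$SD,
               SS_ad = ad$SS, SS_ab = ab$SS,
               PAmax_ad = ad$PAmax, PAmax_ab = ab$PAmax,
               SPALA_ad = ad$SPALA, SPALA_ab = ab$SPALA,
               gsw_max_ad = ad$gsw_max, gsw_max_ab = ab$gsw_max,
               SD_total = tot$SD_total, SPALA_total = tot$SPALA_total,
               g_total = tot$g_total, SS_mean = tot$SS_mean,
               PAmax_mean = tot$PAmax_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
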