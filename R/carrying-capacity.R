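#' Swidden-fallow cultivation factor
#'
#' `C = Fal_yr / Crop_yr + 1`: the multiplier converting actively cropped
#' land into total land tied up by a rotation that crops a plot for
#' `crop_yr` years and rests it for `fal_yr` years.
#'
#' @param fal_yr Fallow years (>= 0).
#' @param crop_yr Cropping years (>= 1).
#' @return The dimensionless cultivation factor.
#' @export
#' @examples
#' cultivation_factor(10, 3)  # 4.333..., the default rotation
cultivation_factor <- function(fal_yr = 10, crop_yr = 3) {
  if (crop_yr < 1) stop("crop_yr must be >= 1", call. = FALSE)
  if (fal_yr < 0) stop("fal_yr must be >= 0", call. = FALSE)
  fal_yr / crop_yr + 1
}

#' Per-capita land requirement for maize cultivation
#'
#' `L_PM = Cons_P * C / L_R` (ha/person): annual consumption times the
#' fallow multiplier, divided by the annual yield per hectare. Consumption is
#' treated as an annual quantity with one harvest per year.
#'
#' @param cons_P Maize consumption (kg/person/yr, default 178.1: two thirds
#'   of an adult's dietary energy supplied by maize).
#' @param C Cultivation factor, see [cultivation_factor()].
#' @param L_R Maize yield (kg/ha/yr), > 0.
#' @return Hectares per person.
#' @export
#' @examples
#' per_capita_maize_land(L_R = 300)   # 2.57 ha at the lowest yield
#' per_capita_maize_land(L_R = 1800)  # 0.43 ha at the highest
per_capita_maize_land <- function(cons_P = 178.1, C = cultivation_factor(),
                                  L_R) {
  if (any(L_R <= 0)) stop("L_R must be > 0", call. = FALSE)
  cons_P * C / L_R
}

#' Per-capita land requirement for fuelwood extraction
#'
#' Fuelwood is harvested sustainably every year with no fallow, so the land
#' requirement is simply demand over yield.
#'
#' @param fuel_demand Fuelwood demand (kg/person/yr, default 700).
#' @param fuel_yield Sustainable fuelwood yield (kg/ha/yr, default 1200).
#' @return Hectares of forested land per person.
#' @export
#' @examples
#' per_capita_fuel_land()  # 0.583 ha/person
per_capita_fuel_land <- function(fuel_demand = 700, fuel_yield = 1200) {
  if (any(fuel_yield <= 0)) stop("fuel_yield must be > 0", call. = FALSE)
  fuel_demand / fuel_yield
}

#' Maximum carrying capacity under a land-allocation scenario
#'
#' Population is limited jointly by maize land and forested fuelwood land:
#' * `savanna_only` — maize only in the savannas: `k = min(S / lpm, F / lpf)`;
#' * `forest_only` — both resources compete for forest, optimally split:
#'   `k = F / (lpm + lpf)`;
#' * `mixed` — savanna maize first, with forest encroachment only when the
#'   system is maize-limited, never below the savanna-only result:
#'   `k = max(min((S + F) / (lpm + lpf), F / lpf), savanna_only)`.
#'
#' Reported as `floor(k)` whole persons.
#'
#' @param areas An [area_summary()] row (or any list with `savanna_area` and
#'   `forest_area` in km2).
#' @param lpm Per-capita maize land (ha/person), see [per_capita_maize_land()].
#' @param lpf Per-capita fuelwood land (ha/person),
#'   see [per_capita_fuel_land()].
#' @param scenario One of `"savanna_only"`, `"forest_only"`, `"mixed"`.
#' @return Carrying capacity `k` (whole persons).
#' @export
capacity <- function(areas, lpm, lpf,
                     scenario = c("savanna_only", "forest_only", "mixed")) {
  scenario <- match.arg(scenario)
  S <- areas$savanna_area * 100  # km2 -> ha
  F_ <- areas$forest_area * 100
  if (S < 0 || F_ < 0) stop("areas must be >= 0", call. = FALSE)
  k <- switch(scenario,
    savanna_only = min(S / lpm, F_ / lpf),
    forest_only = F_ / (lpm + lpf),
    mixed = max(min((S + F_) / (lpm + lpf), F_ / lpf),
                min(S / lpm, F_ / lpf))
  )
  floor(k)
}

#' Carrying-capacity table over maize yields, scenarios and accessibility
#'
#' Evaluates [capacity()] for each maize yield in `L_R_grid` under all three
#' land-allocation scenarios, for the full landscape and (when `sites` is
#' given) for the land within daily walking distance of the sites.
#'
#' @param landscape A [grid_landscape()], or `NULL` when `areas_full` /
#'   `areas_restricted` are supplied directly.
#' @param sites Optional site tibble enabling the walking-restricted panel.
#' @param L_R_grid Maize yields (kg/ha/yr).
#' @param cons_P,fal_yr,crop_yr,fuel_demand,fuel_yield Capacity parameters;
#'   see [per_capita_maize_land()] and [per_capita_fuel_land()].
#' @param radius Walking radius in km.
#' @param areas_full,areas_restricted Optional explicit [area_summary()] rows
#'   overriding landscape-derived areas (e.g. exact published areas).
#' @return A tibble with columns `restricted`, `maize_yield`, `forest_only`,
#'   `savanna_only`, `mixed` plus area columns.
#' @export
capacity_table <- function(landscape = NULL, sites = NULL,
                           L_R_grid = c(300, 600, 900, 1200, 1500, 1800),
                           cons_P = 178.1, fal_yr = 10, crop_yr = 3,
                           fuel_demand = 700, fuel_yield = 1200,
                           radius = 7,
                           areas_full = NULL, areas_restricted = NULL) {
  if (is.null(areas_full)) {
    if (is.null(landscape)) stop("need a landscape or explicit areas",
                                 call. = FALSE)
    areas_full <- area_summary(landscape)
  }
  if (is.null(areas_restricted) && !is.null(sites) && !is.null(landscape)) {
    areas_restricted <- area_summary(landscape,
                                     walking_mask(landscape, sites, radius))
  }
  lpf <- per_capita_fuel_land(fuel_demand, fuel_yield)
  C <- cultivation_factor(fal_yr, crop_yr)
  panel <- function(areas, restricted) {
    purrr::map_dfr(L_R_grid, function(LR) {
      lpm <- per_capita_maize_land(cons_P, C, LR)
      tibble::tibble(
        restricted = restricted,
        maize_yield = LR,
        forest_only = capacity(areas, lpm, lpf, "forest_only"),
        savanna_only = capacity(areas, lpm, lpf, "savanna_only"),
        mixed = capacity(areas, lpm, lpf, "mixed"),
        terrestrial_area = areas$forest_area + areas$savanna_area,
        forest_frac = areas$forest_area /
          (areas$forest_area + areas$savanna_area)
      )
    })
  }
  out <- panel(areas_full, FALSE)
  if (!is.null(areas_restricted)) {
    out <- dplyr::bind_rows(out, panel(areas_restricted, TRUE))
  }
  out
}
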