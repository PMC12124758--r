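#' Build an earthwork inventory with total volumes
#'
#' Converts mound surface areas and the causeway-canal network length into the
#' total earth volumes that had to be excavated and transported. Mound volume
#' uses a surface-area:volume ratio; the network assumes 5 m3 of earth
#' excavated per linear metre. Erosion is applied as observed / (1 - e), i.e.
#' the visible earth is a consistent fraction of what was originally moved.
#'
#' @param mound_areas Numeric vector of mound surface areas (ha).
#' @param ratio Volume per unit surface area (m3 per ha).
#' @param network_length Causeway-canal network length (m).
#' @param per_metre_volume m3 excavated per linear metre of network (default 5).
#' @param erosion_frac Proportion of the original earth since lost, in [0, 1).
#' @return A one-row tibble with `T_m` and `T_c` (total m3 for mounds and
#'   network) plus the inputs.
#' @export
#' @examples
#' build_inventory(mound_areas = c(5, 10), ratio = 30000,
#'                 network_length = 1000)
build_inventory <- function(mound_areas, ratio, network_length,
                            per_metre_volume = 5, erosion_frac = 0) {
  if (any(c(mound_areas, ratio, network_length, per_metre_volume) < 0)) {
    stop("inventory inputs must be >= 0", call. = FALSE)
  }
  if (erosion_frac < 0 || erosion_frac >= 1) {
    stop("erosion_frac must lie in [0, 1)", call. = FALSE)
  }
  tibble::tibble(
    n_mounds = length(mound_areas),
    total_mound_area = sum(mound_areas),
    area_volume_ratio = ratio,
    network_length = network_length,
    per_metre_volume = per_metre_volume,
    erosion_frac = erosion_frac,
    T_m = sum(mound_areas) * ratio / (1 - erosion_frac),
    T_c = network_length * per_metre_volume / (1 - erosion_frac)
  )
}

#' Metabolic rate of loaded walking (Pandolf equation)
#'
#' `1.5 M + 2 (M + Q) (Q / M)^2 + mu (M + Q) (1.5 V^2 + 0.35 V G)`: the
#' standing + load + locomotion cost of a walker of body mass `M` carrying
#' load `Q` at speed `V` up a gradient `G` over terrain factor `mu`.
#'
#' @param M Body mass (kg), > 0.
#' @param Q Carried load (kg), >= 0.
#' @param V Walking speed (km/h), >= 0.
#' @param G Gradient (%), >= 0.
#' @param mu Terrain factor (dimensionless, 1 = treadmill).
#' @return Metabolic rate (W).
#' @export
#' @examples
#' pandolf_rate(M = 65, Q = 0, V = 0, G = 0)  # 1.5 * 65 = 97.5
pandolf_rate <- function(M, Q, V, G, mu = 1) {
  if (any(M <= 0)) stop("M must be > 0", call. = FALSE)
  if (any(c(Q, V, G) < 0)) stop("Q, V, G must be >= 0", call. = FALSE)
  1.5 * M + 2 * (M + Q) * (Q / M)^2 + mu * (M + Q) * (1.5 * V^2 + 0.35 * V * G)
}

#' Walking speed under load at constant energy expenditure
#'
#' Solves for the speed `V` at which a loaded walker on gradient `G` expends
#' the same energy as walking unloaded on the flat at `V_ref` (default 5
#' km/h), by bracketed root-finding of the Pandolf equation on `[0, V_ref]`
#' to 1e-6 km/h.
#'
#' @inheritParams pandolf_rate
#' @param V_ref Unloaded reference walking speed (km/h).
#' @return Loaded speed (km/h).
#' @export
#' @examples
#' loaded_speed(M = 65, Q = 0, G = 0)  # 5: the identity case
loaded_speed <- function(M, Q, G, mu = 1, V_ref = 5) {
  e_ref <- pandolf_rate(M, 0, V_ref, 0, mu)
  f <- function(v) pandolf_rate(M, Q, v, G, mu) - e_ref
  if (f(0) >= 0) {
    stop("infeasible load: even standing exceeds the reference energy",
         call. = FALSE)
  }
  if (f(V_ref) <= 0) return(V_ref)
  stats::uniroot(f, c(0, V_ref), tol = 1e-6)$root
}

#' Daily earth transport rate over a trip of legs
#'
#' One round trip moves `Q / rho` m3; the trip takes `sum(L_i / V_i)` hours
#' over its legs (loaded flat, loaded upslope, unloaded return). The daily
#' rate is volume per trip times trips per `H`-hour workday. Mound and
#' network contexts are evaluated as separate calls.
#'
#' @param Q Carried load (kg).
#' @param rho Soil density (kg/m3, default 1500 for clay-dominated soil).
#' @param legs Data frame or tibble with columns `distance` (km) and
#'   `speed` (km/h); one row per leg.
#' @param H Hours worked per day.
#' @return Transport rate (m3/day).
#' @export
#' @examples
#' transport_rate(Q = 20, legs = tibble::tibble(
#'   distance = c(0.005, 0.005), speed = c(4.36, 5)))
transport_rate <- function(Q, rho = 1500, legs, H = 8) {
  legs <- tibble::as_tibble(legs)
  if (nrow(legs) == 0) stop("empty leg list", call. = FALSE)
  if (any(legs$speed <= 0)) stop("all legs need speed > 0", call. = FALSE)
  (Q / rho) * H / sum(legs$distance / legs$speed)
}

#' Earth volume to be moved per workday
#'
#' Divides a total volume by workdays per year times occupation years: the
#' construction effort is assumed linear over the occupation, 1/Y-th of the
#' total moved annually over D workdays.
#'
#' @param T_total Total volume (m3).
#' @param D Workdays per year (default 18).
#' @param Y Occupation duration in years (default 1000).
#' @return Volume per workday (m3).
#' @export
annual_daily_volume <- function(T_total, D = 18, Y = 1000) {
  if (D <= 0 || Y <= 0) stop("D and Y must be > 0", call. = FALSE)
  T_total / (D * Y)
}

#' Workforce needed to excavate and transport the daily volumes
#'
#' Each component is a daily volume divided by the matching per-person daily
#' rate. The total is the sum of the unrounded components; rounding to whole
#' persons (half-up) happens only in reported columns.
#'
#' @param T_md,T_cd Daily volumes for mounds and network (m3/workday).
#' @param E_mx,E_cx Excavation rates (m3/person/day), mounds and network.
#' @param E_mt,E_ct Transport rates (m3/person/day), mounds and network.
#' @return One-row tibble: unrounded `canal_excavators`, `mound_excavators`,
#'   `canal_transporters`, `mound_transporters`, `total_workforce`.
#' @export
workforce <- function(T_md, T_cd, E_mx, E_mt, E_cx, E_ct) {
  rates <- c(E_mx, E_mt, E_cx, E_ct)
  if (any(rates <= 0)) stop("all rates must be > 0", call. = FALSE)
  ce <- T_cd / E_cx
  me <- T_md / E_mx
  ct <- T_cd / E_ct
  mt <- T_md / E_mt
  tibble::tibble(
    canal_excavators = ce, mound_excavators = me,
    canal_transporters = ct, mound_transporters = mt,
    total_workforce = ce + me + ct + mt
  )
}

#' Population sustaining a given workforce
#'
#' The workforce is assumed to constitute between 20 and 50% of the total
#' population; the population is workforce / ratio on unrounded values.
#'
#' @param P_w Workforce (persons, may be fractional).
#' @param workforce_ratio Workforce as a fraction of population, in (0, 1].
#' @return Population (persons, unrounded).
#' @export
population_from_workforce <- function(P_w, workforce_ratio) {
  if (any(workforce_ratio <= 0 | workforce_ratio > 1)) {
    stop("workforce_ratio must lie in (0, 1]", call. = FALSE)
  }
  P_w / workforce_ratio
}

# round half-up to whole persons (base round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Default labour parameters for the energetics sweep
#'
#' @param Q Carried load (kg). @param M Body mass (kg).
#' @param H Hours worked per day. @param V_unloaded Unloaded speed (km/h).
#' @param mu Terrain factor. @param G_up Upslope gradient (%) onto the mound.
#' @param rho Soil density (kg/m3).
#' @param tool_factor Metal-tool to digging-stick efficiency divisor.
#' @param D Workdays per year. @param Y Occupation duration (years).
#' @param mound_flat_m,mound_up_m Loaded mound legs: flat and upslope (m).
#' @param network_m Loaded network leg (m); return legs are unloaded.
#' @return A list of class `labor_params`.
#' @export
labor_params <- function(Q = 20, M = 65, H = 8, V_unloaded = 5, mu = 1,
                         G_up = 20, rho = 1500, tool_factor = 2.7,
                         D = 18, Y = 1000,
                         mound_flat_m = 50, mound_up_m = 10, network_m = 5) {
  structure(as.list(environment()), class = "labor_params")
}

# transport rates (m3/day) for the mound and network leg contexts
transport_rates_from_params <- function(lp) {
  v_flat <- loaded_speed(lp$M, lp$Q, 0, lp$mu, lp$V_unloaded)
  v_up <- loaded_speed(lp$M, lp$Q, lp$G_up, lp$mu, lp$V_unloaded)
  mound_legs <- tibble::tibble(
    distance = c(lp$mound_flat_m, lp$mound_up_m,
                 lp$mound_flat_m + lp$mound_up_m) / 1000,
    speed = c(v_flat, v_up, lp$V_unloaded)
  )
  network_legs <- tibble::tibble(
    distance = c(lp$network_m, lp$network_m) / 1000,
    speed = c(v_flat, lp$V_unloaded)
  )
  list(E_mt = transport_rate(lp$Q, lp$rho, mound_legs, lp$H),
       E_ct = transport_rate(lp$Q, lp$rho, network_legs, lp$H))
}

#' Sweep workforce and population estimates over excavation rates
#'
#' For each digging-stick excavation rate the daily mound and network volumes
#' are converted into excavator and transporter head counts, a total labour
#' force, and population columns at workforce:population ratios 1:2 to 1:5.
#' Head counts are rounded half-up for reporting; totals and population
#' columns are computed from unrounded components. Transport rates come from
#' the Pandolf-derived leg speeds in `labor` unless overridden.
#'
#' @param inventory A [build_inventory()] row (uses `T_m`, `T_c`).
#' @param labor A [labor_params()].
#' @param rates Excavation-rate grid (m3/person/day), default 0.3 to 1.4 by
#'   0.1 (the metal-tool experimental range divided by the digging-stick
#'   factor, as printed).
#' @param E_mt,E_ct Optional transport-rate overrides (m3/person/day), e.g.
#'   back-derived from published head counts.
#' @param ratios Workforce:population ratios to report (fractions).
#' @return A tibble of class `energetics_sweep`, one row per rate, with
#'   rounded reporting columns; unrounded components kept in `.unrounded_*`
#'   columns. A `person_days` attribute carries min/max person-day totals.
#' @export
energetics_sweep <- function(inventory, labor = labor_params(),
                             rates = seq(0.3, 1.4, by = 0.1),
                             E_mt = NULL, E_ct = NULL,
                             ratios = c(0.5, 1 / 3, 0.25, 0.2)) {
  if (any(rates <= 0)) stop("rates must be > 0", call. = FALSE)
  T_md <- annual_daily_volume(inventory$T_m, labor$D, labor$Y)
  T_cd <- annual_daily_volume(inventory$T_c, labor$D, labor$Y)
  if (is.null(E_mt) || is.null(E_ct)) {
    tr <- transport_rates_from_params(labor)
    if (is.null(E_mt)) E_mt <- tr$E_mt
    if (is.null(E_ct)) E_ct <- tr$E_ct
  }
  zero <- T_md == 0 && T_cd == 0
  rows <- purrr::map_dfr(sort(rates, decreasing = TRUE), function(rate) {
    w <- if (zero) {
      tibble::tibble(canal_excavators = 0, mound_excavators = 0,
                     canal_transporters = 0, mound_transporters = 0,
                     total_workforce = 0)
    } else {
      workforce(T_md, T_cd, E_mx = rate, E_mt = E_mt,
                E_cx = rate, E_ct = E_ct)
    }
    pops <- population_from_workforce(w$total_workforce, ratios)
    out <- tibble::tibble(
      excavation_rate = rate,
      canal_excavators = round_half_up(w$canal_excavators),
      mound_excavators = round_half_up(w$mound_excavators),
      canal_transporters = round_half_up(w$canal_transporters),
      mound_transporters = round_half_up(w$mound_transporters),
      total_workforce = round_half_up(w$total_workforce)
    )
    for (i in seq_along(ratios)) {
      out[[paste0("population_1_", round(1 / ratios[i]))]] <-
        round_half_up(pops[i])
    }
    out$.unrounded_total <- w$total_workforce
    out
  })
  total_volume <- inventory$T_m + inventory$T_c
  person_days <- tibble::tibble(
    quantity = c("excavation_min", "excavation_max", "transport",
                 "network_min", "network_max", "mounds_min", "mounds_max",
                 "total_min", "total_max"),
    person_days = c(
      total_volume / max(rates), total_volume / min(rates),
      inventory$T_m / E_mt + inventory$T_c / E_ct,
      inventory$T_c / max(rates) + inventory$T_c / E_ct,
      inventory$T_c / min(rates) + inventory$T_c / E_ct,
      inventory$T_m / max(rates) + inventory$T_m / E_mt,
      inventory$T_m / min(rates) + inventory$T_m / E_mt,
      total_volume / max(rates) + inventory$T_m / E_mt + inventory$T_c / E_ct,
      total_volume / min(rates) + inventory$T_m / E_mt + inventory$T_c / E_ct
    )
  )
  structure(rows,
            person_days = person_days,
            daily_volumes = c(T_md = T_md, T_cd = T_cd),
            transport_rates = c(E_mt = E_mt, E_ct = E_ct),
            class = c("energetics_sweep", class(rows)))
}

#' @export
#' @rdname energetics_sweep
#' @param x An `energetics_sweep`.
#' @param ... Unused.
person_days <- function(x, ...) attr(x, "person_days")
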