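#' Configuration for the settlement simulator
#'
#' One value per behavioural parameter of the household-level settlement
#' simulator. Continuous parameters correspond to the experiment design's
#' sampled variables (see [parameter_space()] for their ranges); the engine
#' itself accepts any value in the natural domain.
#'
#' @param max_set_density Maximum number of active settlements tolerated
#'   within `migration_distance` of a group's home before founding is barred.
#' @param mig_dist_cost,mig_dist_bonus Weights of the distance cost / bonus
#'   score components (`D_W`, `Di_W`).
#' @param mig_lobe_bonus Weight of the fertile-sediment productivity bonus
#'   (`Pd_w`).
#' @param mig_pop_bonus,mig_pop_cost Weights of the crowding bonus / cost
#'   components (`Pop_W`, `Cr_W`).
#' @param migration_distance Maximum migration distance `R_m` (km).
#' @param migration_rate Baseline per-settlement migration probability `Mi_u`.
#' @param new_settlement_prob Probability a migrating group first attempts to
#'   found a new settlement rather than join an existing one.
#' @param prob_household_birth Annual birth probability `b_h` for an eligible
#'   two-adult household.
#' @param protein_modifier Maximum dietary share supplied by animal protein;
#'   scales the protein demand.
#' @param settlement_base_capacity Full mound capacity in households.
#' @param start_population_modifier Multiplier on the 10 households per
#'   initial settlement.
#' @param yr_10 Years between successive 10%-of-base capacity increments as
#'   the mound is built.
#' @param forage_die,forest_restrict,fuelwood_die,intentional_agroforestry,lobe_restrict,maize_die,palm_die,protein_die
#'   Boolean switches: `*_die` turns a resource deficit lethal;
#'   `forest_restrict` / `lobe_restrict` constrain settlement cells to forest
#'   cover / the fertile lobe; `intentional_agroforestry` lets forest cells
#'   cleared for maize still yield tree crops.
#' @param land_for_cultivation Where maize may be grown: `"Forest Only"`,
#'   `"Savanna Only"` or `"Forest and Savanna"`.
#' @param n_candidate_cells Number of seeded-random candidate cells scored
#'   when founding a settlement.
#' @param seed RNG seed used by [init_model()].
#' @return A list of class `abm_config`.
#' @export
abm_config <- function(max_set_density = 10,
                       mig_dist_cost = 0.5,
                       mig_lobe_bonus = 0.5,
                       mig_pop_bonus = 0.5,
                       mig_pop_cost = 0.5,
                       mig_dist_bonus = 0.5,
                       migration_distance = 20,
                       migration_rate = 0.05,
                       new_settlement_prob = 0.5,
                       prob_household_birth = 0.2,
                       protein_modifier = 0.4,
                       settlement_base_capacity = 100,
                       start_population_modifier = 1,
                       yr_10 = 100,
                       forage_die = FALSE,
                       forest_restrict = TRUE,
                       fuelwood_die = TRUE,
                       intentional_agroforestry = FALSE,
                       lobe_restrict = FALSE,
                       maize_die = TRUE,
                       palm_die = FALSE,
                       protein_die = FALSE,
                       land_for_cultivation = "Forest and Savanna",
                       n_candidate_cells = 100,
                       seed = 1L) {
  land_for_cultivation <- match.arg(
    land_for_cultivation,
    c("Forest Only", "Savanna Only", "Forest and Savanna"))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "abm_config")
}

# Table-2 parameter names (hyphenated) <-> abm_config field names
config_name_map <- function() {
  c("max-set-density" = "max_set_density",
    "mig-dist-cost" = "mig_dist_cost",
    "mig-lobe-bonus" = "mig_lobe_bonus",
    "mig-pop-bonus" = "mig_pop_bonus",
    "mig-pop-cost" = "mig_pop_cost",
    "mig-dist-bonus" = "mig_dist_bonus",
    "migration-distance" = "migration_distance",
    "migration-rate" = "migration_rate",
    "new-settlement-prob" = "new_settlement_prob",
    "prob-household-birth" = "prob_household_birth",
    "protein-modifier" = "protein_modifier",
    "settlement-base-capacity" = "settlement_base_capacity",
    "start-population-modifier" = "start_population_modifier",
    "yr-10%" = "yr_10",
    "forage-die" = "forage_die",
    "forest-restrict" = "forest_restrict",
    "fuelwood-die" = "fuelwood_die",
    "intentional-agroforestry" = "intentional_agroforestry",
    "lobe-restrict" = "lobe_restrict",
    "maize-die" = "maize_die",
    "palm-die" = "palm_die",
    "protein-die" = "protein_die",
    "land-for-cultivation" = "land_for_cultivation")
}

#' Read a simulator configuration from YAML
#'
#' The YAML file uses the hyphenated experiment-table parameter names
#' (`max-set-density`, `prob-household-birth`, `yr-10%`, ...); unknown keys
#' are rejected, omitted ones keep the [abm_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return An [abm_config()].
#' @export
read_abm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  map <- config_name_map()
  known <- c(names(map), "seed", "n_candidate_cells")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- vals
  hy <- intersect(names(vals), names(map))
  names(args)[match(hy, names(args))] <- map[hy]
  do.call(abm_config, args)
}

#' Age-specific annual mortality schedule
#'
#' A vector of annual death probabilities indexed by age 0..80, with certain
#' death at 80 and beyond. The default is a Siler schedule
#' `a1 exp(-b1 age) + a2 + a3 exp(b3 age)` — high infant mortality, a low
#' background hazard, and an exponentially rising senescent hazard —
#' calibrated so roughly 40% of a birth cohort survives to age 70, in line
#' with the subsistence-population life tables the simulator's demography is
#' modelled on. Any age-indexed table can be loaded with
#' `mortality_schedule(read.csv(...)$Mo)`.
#'
#' @param Mo Optional numeric vector of death probabilities for ages
#'   `0..(length(Mo) - 1)`; the schedule is padded/truncated to ages 0..80
#'   and forced to 1 at 80.
#' @param a1,b1,a2,a3,b3 Siler parameters used when `Mo` is `NULL`.
#' @return Numeric vector of length 81 (ages 0..80) of class
#'   `mortality_schedule`.
#' @export
#' @examples
#' sched <- mortality_schedule()
#' sched[81]  # age 80: certain death
mortality_schedule <- function(Mo = NULL, a1 = 0.15, b1 = 0.9,
                               a2 = 0.004, a3 = 1e-4, b3 = 0.085) {
  if (is.null(Mo)) {
    age <- 0:80
    Mo <- a1 * exp(-b1 * age) + a2 + a3 * exp(b3 * age)
  }
  Mo <- c(Mo, rep(Mo[length(Mo)], max(0, 81 - length(Mo))))[1:81]
  Mo <- pmin(pmax(Mo, 0), 1)
  Mo[81] <- 1
  structure(Mo, class = "mortality_schedule")
}

#' Per-resource demand and yield parameters
#'
#' The five subsistence resources the simulator tracks. Maize and fuelwood
#' demands/yields match the carrying-capacity defaults; tree crops, palm
#' leaves and animal protein are plausible field values exposed for
#' configuration. Protein demand is the full-diet equivalent and is scaled by
#' the configuration's `protein_modifier` at run time. Children count as
#' `child_frac` of an adult's demand.
#'
#' @param maize_demand,maize_yield kg/person/yr and kg/ha/yr for maize.
#' @param crop_yr,fal_yr Cropping and fallow years of the maize rotation.
#' @param forage_demand,forage_yield Foraged tree crops (forest cells).
#' @param fuel_demand,fuel_yield Fuelwood (forest cells).
#' @param palm_demand,palm_yield Palm leaves (forest cells).
#' @param protein_demand,protein_yield Animal protein, full-diet equivalent
#'   (any terrestrial cell).
#' @param child_frac Child demand as a fraction of an adult's.
#' @return A list of class `resource_params`.
#' @export
resource_params <- function(maize_demand = 178.1, maize_yield = 900,
                            crop_yr = 3, fal_yr = 10,
                            forage_demand = 60, forage_yield = 200,
                            fuel_demand = 700, fuel_yield = 1200,
                            palm_demand = 30, palm_yield = 120,
                            protein_demand = 250, protein_yield = 8,
                            child_frac = 0.5) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) stop("demands and yields must be >= 0", call. = FALSE)
  structure(p, class = "resource_params")
}

#' Annual birth draw for a two-adult household
#'
#' A household with two adults produces a child this year iff a uniform draw
#' is at most `b_h` and the younger adult (assumed female) is under 50.
#'
#' @param younger_adult_age Age of the household's younger adult.
#' @param b_h Annual birth probability.
#' @return `TRUE` if a child is born.
#' @export
try_birth <- function(younger_adult_age, b_h) {
  stats::runif(length(younger_adult_age)) <= b_h & younger_adult_age < 50
}

#' Annual mortality draw for individuals
#'
#' Death occurs iff a uniform draw is at most the schedule's probability for
#' the individual's age; everyone aged 80 or more dies.
#'
#' @param age Integer ages.
#' @param schedule A [mortality_schedule()].
#' @return Logical vector: `TRUE` = dead.
#' @export
apply_mortality <- function(age, schedule = mortality_schedule()) {
  if (any(age < 0)) stop("negative age", call. = FALSE)
  mo <- unclass(schedule)[pmin(age, 80L) + 1L]
  stats::runif(length(age)) <= mo | age >= 80
}

#' Per-settlement migration-event probability
#'
#' `min(Mi_u * P_st / cap_t, 2 Mi_u)`, gated to zero unless the settlement
#' population exceeds half its current capacity and it has at least five
#' member households.
#'
#' @param P_st Settlement population (households).
#' @param cap_t Current settlement capacity (households), > 0.
#' @param Mi_u Baseline migration rate.
#' @param n_households Member household count used for the five-household
#'   gate; defaults to `P_st`.
#' @return Probability of a migration event this year.
#' @export
migration_probability <- function(P_st, cap_t, Mi_u, n_households = P_st) {
  if (any(cap_t <= 0)) stop("cap_t must be > 0", call. = FALSE)
  p <- pmin(Mi_u * P_st / cap_t, 2 * Mi_u)
  p[P_st <= cap_t / 2 | n_households < 5] <- 0
  p
}

#' Score components for joining or founding a settlement
#'
#' Components (each scaled by its weight and 100): productivity
#' `Pd_sc = Pd_w * 100 * Pd` from the fertile flag; distance cost/bonus
#' `D_sc = D_W * 100 * D^2 / R_m^2` and `Di_sc = Di_W * 100 * D^2 / R_m^2`;
#' crowding bonus/cost `Pop_sc = Pop_W * 100 * P_st^2 / cap_t^2` and
#' `Cr_sc = Cr_W * 100 * P_st^2 / cap_t^2`. The habitability score of a
#' candidate settlement is `Pd_sc - Cr_sc + Pop_sc - D_sc + Di_sc`; the
#' suitability score of a candidate cell is `Pd_sc - D_sc + Di_sc`.
#'
#' @param Pd 0/1 fertile flag of the candidate location.
#' @param D Distance from the home settlement (km), at most `R_m`.
#' @param P_st,cap_t Candidate settlement's population and capacity
#'   (households); `cap_t` must be > 0.
#' @param weights List with `Pd_w`, `D_W`, `Di_W`, `Pop_W`, `Cr_W`.
#' @param R_m Maximum migration distance (km).
#' @return Numeric score(s).
#' @export
habitability_score <- function(Pd, D, P_st, cap_t, weights, R_m) {
  if (any(cap_t <= 0)) stop("candidate settlement has zero capacity",
                            call. = FALSE)
  dist_term <- 100 * D^2 / R_m^2
  pop_term <- 100 * P_st^2 / cap_t^2
  weights$Pd_w * 100 * Pd - weights$Cr_W * pop_term +
    weights$Pop_W * pop_term - weights$D_W * dist_term +
    weights$Di_W * dist_term
}

#' @rdname habitability_score
#' @export
suitability_score <- function(Pd, D, weights, R_m) {
  dist_term <- 100 * D^2 / R_m^2
  weights$Pd_w * 100 * Pd - weights$D_W * dist_term +
    weights$Di_W * dist_term
}

# weights list from a config
config_weights <- function(config) {
  list(Pd_w = config$mig_lobe_bonus, D_W = config$mig_dist_cost,
       Di_W = config$mig_dist_bonus, Pop_W = config$mig_pop_bonus,
       Cr_W = config$mig_pop_cost)
}

#' Current mound capacity given time since founding
#'
#' Capacity starts at 10% of the full mound capacity and gains another 10%
#' every `ceiling(yr_10)` years since founding while the settlement is
#' active, clamped to the full capacity. Abandoned settlements do not grow
#' but retain accrued capacity (earth construction is durable).
#'
#' @param base_capacity Full capacity (households).
#' @param founded_year Founding timestep.
#' @param year Current timestep.
#' @param yr_10 Years per 10% increment.
#' @param active Is the settlement active? Inactive settlements keep
#'   `current_capacity` unchanged.
#' @param current_capacity Accrued capacity, used when `active` is `FALSE`.
#' @return Current capacity (households).
#' @export
grow_capacity <- function(base_capacity, founded_year, year, yr_10,
                          active = TRUE, current_capacity = NULL) {
  grown <- base_capacity * 0.1 *
    (1 + floor((year - founded_year) / ceiling(yr_10)))
  grown <- pmin(grown, base_capacity)
  if (is.null(current_capacity)) current_capacity <- base_capacity * 0.1
  out <- ifelse(active, pmax(grown, current_capacity), current_capacity)
  out
}
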