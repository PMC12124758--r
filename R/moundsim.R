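# Engine internals ------------------------------------------------------------
# State layout (class "abm_state"): flat parallel vectors for people
# (p_birth, p_hh, p_founder), households (h_settlement, NA = dissolved),
# settlements (s_row, s_col, s_base, s_cap, s_founded, s_active) and cells
# (cover/fertile/elevated as vectors, maize rotation state, nearest-settlement
# assignment). All randomness flows through the global RNG seeded at init, so
# identical config + landscape + seed gives a bitwise-identical trajectory.

cell_index <- function(row, col, n_rows) (col - 1L) * n_rows + row

resample <- function(x, n = 1) x[sample.int(length(x), n)]

# cells eligible to host a settlement under the config's restrictions
settlement_eligible <- function(state) {
  cc <- cover_codes()
  ok <- state$elevated & state$cover != cc[["WATER"]]
  if (state$config$forest_restrict) ok <- ok & state$cover == cc[["FOREST"]]
  if (state$config$lobe_restrict) ok <- ok & state$fertile
  ok
}

settlement_members <- function(state) {
  n_s <- length(state$s_row)
  if (n_s == 0 || length(state$h_settlement) == 0) return(integer(n_s))
  alive <- !is.na(state$h_settlement)
  tabulate(state$h_settlement[alive], nbins = n_s)
}

#' Initialise the settlement simulator
#'
#' Spawns 10 settlements on eligible cells (elevated, respecting the
#' forest/lobe restriction flags), each with `round(10 *
#' start_population_modifier)` two-adult households whose adults' ages are
#' drawn uniformly on 16..40. Initial capacity is 10% of the full mound
#' capacity. Seeds the RNG from the config.
#'
#' @param landscape A [grid_landscape()].
#' @param config An [abm_config()].
#' @param resources A [resource_params()].
#' @param schedule A [mortality_schedule()].
#' @return An object of class `abm_state` at year 0.
#' @export
init_model <- function(landscape, config, resources = resource_params(),
                       schedule = mortality_schedule()) {
  set.seed(config$seed)
  d <- dim(landscape)
  state <- structure(list(
    year = 0L, config = config, resources = resources, schedule = schedule,
    n_rows = d[1], n_cols = d[2],
    cover = as.vector(landscape$cover),
    fertile = as.vector(landscape$fertile),
    elevated = as.vector(landscape$elevated),
    p_birth = integer(0), p_hh = integer(0), p_founder = logical(0),
    h_settlement = integer(0),
    s_row = integer(0), s_col = integer(0), s_base = numeric(0),
    s_cap = numeric(0), s_founded = integer(0), s_active = logical(0),
    crop_state = integer(d[1] * d[2]), crop_year = integer(d[1] * d[2]),
    crop_owner = integer(d[1] * d[2]),
    assign = integer(d[1] * d[2]), assign_dirty = TRUE,
    last_stats = NULL
  ), class = "abm_state")

  elig <- which(settlement_eligible(state))
  n_start <- 10L
  if (length(elig) < n_start) {
    stop("insufficient eligible cells to spawn ", n_start, " settlements",
         call. = FALSE)
  }
  cells <- resample(elig, n_start)
  state$s_row <- ((cells - 1L) %% d[1]) + 1L
  state$s_col <- ((cells - 1L) %/% d[1]) + 1L
  state$s_base <- rep(config$settlement_base_capacity, n_start)
  state$s_cap <- rep(0.1 * config$settlement_base_capacity, n_start)
  state$s_founded <- rep(0L, n_start)
  state$s_active <- rep(TRUE, n_start)

  n_hh_per <- round(10 * config$start_population_modifier)
  n_hh <- n_start * n_hh_per
  state$h_settlement <- rep(seq_len(n_start), each = n_hh_per)
  ages <- sample(16:40, 2L * n_hh, replace = TRUE)
  state$p_birth <- as.integer(-ages)
  state$p_hh <- rep(seq_len(n_hh), each = 2L)
  state$p_founder <- rep(TRUE, 2L * n_hh)
  state
}

# drop people flagged dead, then dissolve now-empty households
remove_people <- function(state, dead) {
  if (!any(dead)) return(state)
  state$p_birth <- state$p_birth[!dead]
  state$p_hh <- state$p_hh[!dead]
  state$p_founder <- state$p_founder[!dead]
  occupied <- tabulate(state$p_hh, nbins = length(state$h_settlement))
  empty <- occupied == 0 & !is.na(state$h_settlement)
  if (any(empty)) state$h_settlement[empty] <- NA_integer_
  state
}

# nearest-settlement cell assignment within migration_distance
refresh_assignment <- function(state) {
  if (!state$assign_dirty) return(state)
  n_rows <- state$n_rows; n_cols <- state$n_cols
  best <- rep(Inf, n_rows * n_cols)
  assign <- integer(n_rows * n_cols)
  members <- settlement_members(state)
  span <- floor(state$config$migration_distance / 0.1)
  for (s in which(members > 0)) {
    r0 <- state$s_row[s]; c0 <- state$s_col[s]
    rr <- max(1L, r0 - span):min(n_rows, r0 + span)
    cs <- max(1L, c0 - span):min(n_cols, c0 + span)
    d2 <- outer((rr - r0)^2, (cs - c0)^2, `+`)
    idx <- as.vector(outer(rr, (cs - 1L) * n_rows, `+`))
    d2v <- as.vector(d2)
    ok <- d2v <= span^2 & d2v < best[idx]
    assign[idx[ok]] <- s
    best[idx[ok]] <- d2v[ok]
  }
  state$assign <- assign
  state$assign_dirty <- FALSE
  state
}

#' Resource claiming, harvest and deficit mortality
#'
#' Each settlement pools the demands of its member households (children at
#' the configured fraction of adult demand) and claims unclaimed eligible
#' patches within the migration radius: maize patches respect the
#' land-for-cultivation switch and the crop/fallow rotation (cropped for
#' `crop_yr` years, then fallow and unclaimable for `fal_yr` years); the
#' forest resources (tree crops, fuelwood, palm leaves) draw on uncleared
#' forest patches and animal protein on any terrestrial patch in the
#' settlement's catchment. Per-resource deficit fractions
#' `d = max(0, 1 - supply/demand)` are computed; where the matching `*_die`
#' flag is set, every member of a deficient settlement dies independently
#' with probability `d`.
#'
#' @param state An `abm_state`.
#' @return The updated state; per-resource deficits and deficit deaths are
#'   stored in `state$last_stats`.
#' @export
harvest_and_starve <- function(state) {
  cfg <- state$config; res <- state$resources
  cc <- cover_codes()
  year <- state$year
  state <- refresh_assignment(state)

  # rotation bookkeeping: crops age into fallow, fallow recovers
  cropped <- state$crop_state == 1L
  to_fallow <- cropped & (year - state$crop_year >= res$crop_yr)
  if (any(to_fallow)) {
    state$crop_state[to_fallow] <- 2L
    state$crop_year[to_fallow] <- year
  }
  fallow <- state$crop_state == 2L
  recovered <- fallow & (year - state$crop_year >= res$fal_yr)
  if (any(recovered)) {
    state$crop_state[recovered] <- 0L
    state$crop_owner[recovered] <- 0L
  }

  n_s <- length(state$s_row)
  members <- settlement_members(state)
  if (sum(members) == 0 || length(state$p_birth) == 0) {
    state$last_stats <- list(deficits = NULL, deficit_deaths = integer(0))
    return(state)
  }
  hh_set <- state$h_settlement[state$p_hh]
  ages <- year - state$p_birth
  demand_w <- ifelse(ages >= 16, 1, res$child_frac)
  equiv <- vapply(seq_len(n_s),
                  function(s) sum(demand_w[hh_set == s]), numeric(1))

  allowed_cover <- switch(cfg$land_for_cultivation,
    "Forest Only" = cc[["FOREST"]],
    "Savanna Only" = cc[["SAVANNA"]],
    "Forest and Savanna" = c(cc[["SAVANNA"]], cc[["FOREST"]]))

  maize_supply <- numeric(n_s)
  for (s in which(equiv > 0)) {
    demand_kg <- res$maize_demand * equiv[s]
    own <- state$crop_state == 1L & state$crop_owner == s
    have <- sum(own) * res$maize_yield
    if (have < demand_kg) {
      need <- ceiling((demand_kg - have) / res$maize_yield)
      free <- state$assign == s & state$crop_state == 0L &
        state$cover %in% allowed_cover
      # savanna claimed before forest encroachment
      cand <- c(which(free & state$cover == cc[["SAVANNA"]]),
                which(free & state$cover == cc[["FOREST"]]))
      take <- cand[seq_len(min(need, length(cand)))]
      if (length(take) > 0) {
        state$crop_state[take] <- 1L
        state$crop_year[take] <- year
        state$crop_owner[take] <- s
        have <- have + length(take) * res$maize_yield
      }
    } else if (have - demand_kg >= res$maize_yield) {
      surplus <- floor((have - demand_kg) / res$maize_yield)
      own_idx <- which(own)
      drop <- own_idx[seq(length(own_idx) - surplus + 1L, length(own_idx))]
      state$crop_state[drop] <- 2L  # released plots rest as fallow
      state$crop_year[drop] <- year
      have <- have - surplus * res$maize_yield
    }
    maize_supply[s] <- have
  }

  assign_s <- state$assign
  forest_free <- state$cover == cc[["FOREST"]] & state$crop_state == 0L
  terr <- state$cover != cc[["WATER"]]
  cnt_forest <- tabulate(assign_s[forest_free], nbins = n_s)
  cnt_terr <- tabulate(assign_s[terr], nbins = n_s)
  cnt_agrofor <- if (cfg$intentional_agroforestry) {
    agro <- state$cover == cc[["FOREST"]] & state$crop_state == 1L
    tabulate(state$crop_owner[agro], nbins = n_s)
  } else numeric(n_s)

  deficit <- function(supply, demand) {
    d <- rep(0, n_s)
    pos <- demand > 0
    d[pos] <- pmax(0, 1 - supply[pos] / demand[pos])
    d
  }
  defs <- list(
    maize = deficit(maize_supply, res$maize_demand * equiv),
    forage = deficit((cnt_forest + cnt_agrofor) * res$forage_yield,
                     res$forage_demand * equiv),
    fuelwood = deficit(cnt_forest * res$fuel_yield, res$fuel_demand * equiv),
    palm = deficit(cnt_forest * res$palm_yield, res$palm_demand * equiv),
    protein = deficit(cnt_terr * res$protein_yield,
                      res$protein_demand * cfg$protein_modifier * equiv)
  )
  die_flags <- c(maize = cfg$maize_die, forage = cfg$forage_die,
                 fuelwood = cfg$fuelwood_die, palm = cfg$palm_die,
                 protein = cfg$protein_die)
  deficit_deaths <- stats::setNames(integer(length(defs)), names(defs))
  for (r in names(defs)) {
    if (!die_flags[[r]] || all(defs[[r]] == 0)) next
    hh_set_now <- state$h_settlement[state$p_hh]
    p_die <- defs[[r]][hh_set_now]
    dead <- stats::runif(length(p_die)) <= p_die
    deficit_deaths[[r]] <- sum(dead)
    state <- remove_people(state, dead)
    if (length(state$p_birth) == 0) break
  }
  state$last_stats <- list(deficits = defs, deficit_deaths = deficit_deaths)
  state
}

#' Execute a migration event for one settlement
#'
#' A group of `max(5, households above current capacity)` households is drawn
#' uniformly from the settlement. With probability `new_settlement_prob` the
#' group first attempts to found a new settlement (requires fewer than
#' `max_set_density` active settlements within the migration radius of home,
#' and an eligible candidate cell); otherwise it first attempts to join an
#' existing settlement within range with spare capacity (abandoned
#' settlements may be re-occupied and retain their accrued capacity). On
#' failure the other strategy is attempted once; on double failure the state
#' is unchanged. Candidates are scored with [suitability_score()] /
#' [habitability_score()]; ties are broken by a seeded uniform draw.
#'
#' @param state An `abm_state`.
#' @param s Settlement id experiencing the event.
#' @return The updated state.
#' @export
execute_migration <- function(state, s) {
  cfg <- state$config
  hh_ids <- which(!is.na(state$h_settlement) & state$h_settlement == s)
  if (length(hh_ids) == 0) return(state)
  group_n <- min(length(hh_ids),
                 max(5L, ceiling(length(hh_ids) - state$s_cap[s])))
  group <- resample(hh_ids, group_n)
  w <- config_weights(cfg)
  R_m <- cfg$migration_distance
  home_r <- state$s_row[s]; home_c <- state$s_col[s]
  members <- settlement_members(state)

  try_found <- function(state) {
    d_set <- 0.1 * sqrt((state$s_row - home_r)^2 + (state$s_col - home_c)^2)
    n_active_within <- sum(state$s_active & d_set <= R_m)
    if (n_active_within >= cfg$max_set_density) return(NULL)
    span <- floor(R_m / 0.1)
    rr <- max(1L, home_r - span):min(state$n_rows, home_r + span)
    cs <- max(1L, home_c - span):min(state$n_cols, home_c + span)
    idx <- as.vector(outer(rr, (cs - 1L) * state$n_rows, `+`))
    d2 <- as.vector(outer((rr - home_r)^2, (cs - home_c)^2, `+`))
    elig <- settlement_eligible(state)[idx] & d2 <= span^2
    taken <- cell_index(state$s_row, state$s_col, state$n_rows)
    elig[idx %in% taken] <- FALSE
    cand <- idx[elig]
    if (length(cand) == 0) return(NULL)
    pick <- resample(seq_along(cand), min(cfg$n_candidate_cells, length(cand)))
    cand <- cand[pick]
    d_cand <- 0.1 * sqrt(d2[elig][pick])
    sc <- suitability_score(as.numeric(state$fertile[cand]), d_cand, w, R_m)
    best <- which(sc == max(sc))
    winner <- cand[resample(best)]
    state$s_row <- c(state$s_row, ((winner - 1L) %% state$n_rows) + 1L)
    state$s_col <- c(state$s_col, ((winner - 1L) %/% state$n_rows) + 1L)
    state$s_base <- c(state$s_base, cfg$settlement_base_capacity)
    state$s_cap <- c(state$s_cap, 0.1 * cfg$settlement_base_capacity)
    state$s_founded <- c(state$s_founded, state$year)
    state$s_active <- c(state$s_active, TRUE)
    state$h_settlement[group] <- length(state$s_row)
    state$assign_dirty <- TRUE
    state
  }

  try_join <- function(state) {
    d_set <- 0.1 * sqrt((state$s_row - home_r)^2 + (state$s_col - home_c)^2)
    cand <- which(seq_along(state$s_row) != s & d_set <= R_m &
                    members < state$s_cap)
    if (length(cand) == 0) return(NULL)
    pd <- as.numeric(state$fertile[cell_index(state$s_row[cand],
                                              state$s_col[cand],
                                              state$n_rows)])
    sc <- habitability_score(pd, d_set[cand], members[cand],
                             state$s_cap[cand], w, R_m)
    best <- which(sc == max(sc))
    target <- cand[resample(best)]
    state$h_settlement[group] <- target
    if (!state$s_active[target]) {
      state$s_active[target] <- TRUE
      state$assign_dirty <- TRUE
    }
    state
  }

  first_found <- stats::runif(1) <= cfg$new_settlement_prob
  attempts <- if (first_found) list(try_found, try_join) else
    list(try_join, try_found)
  for (f in attempts) {
    out <- f(state)
    if (!is.null(out)) {
      out$assign_dirty <- TRUE
      return(out)
    }
  }
  state
}

#' Advance the simulator by one year
#'
#' Applies the phases in fixed order: ageing, age-specific mortality,
#' household formation (eligible 16-year-olds pair within their settlement,
#' oldest first), births, resource claiming/harvest with deficit mortality,
#' migration events, then capacity growth and settlement bookkeeping.
#' Newborns do not consume in their birth year (births precede the harvest
#' in the ledger but the harvest uses pre-birth demand weights via age 0
#' counting as a child).
#'
#' @param state An `abm_state`.
#' @return The updated state; `state$last_stats` holds the year's deaths and
#'   deficits.
#' @export
abm_step <- function(state) {
  cfg <- state$config
  state$year <- state$year + 1L
  year <- state$year

  # mortality
  deaths_age <- 0L
  if (length(state$p_birth) > 0) {
    ages <- year - state$p_birth
    dead <- apply_mortality(ages, state$schedule)
    deaths_age <- sum(dead)
    state <- remove_people(state, dead)
  }

  # household formation: grown children pair within their settlement
  if (length(state$p_birth) > 0) {
    ages <- year - state$p_birth
    eligible <- which(!state$p_founder & ages >= 16)
    if (length(eligible) >= 2) {
      set_of <- state$h_settlement[state$p_hh[eligible]]
      for (s in unique(set_of[!is.na(set_of)])) {
        cand <- eligible[!is.na(set_of) & set_of == s]
        cand <- cand[order(-(year - state$p_birth[cand]), cand)]
        n_pairs <- length(cand) %/% 2L
        if (n_pairs == 0) next
        for (k in seq_len(n_pairs)) {
          pair <- cand[c(2L * k - 1L, 2L * k)]
          state$h_settlement <- c(state$h_settlement, s)
          new_hh <- length(state$h_settlement)
          state$p_hh[pair] <- new_hh
          state$p_founder[pair] <- TRUE
        }
      }
    }
  }

  # births: two-adult households, younger adult under 50
  births <- 0L
  if (length(state$p_birth) > 0) {
    founders <- which(state$p_founder)
    if (length(founders) > 0) {
      hh_f <- state$p_hh[founders]
      n_hh <- length(state$h_settlement)
      n_ad <- tabulate(hh_f, nbins = n_hh)
      two_adult <- which(n_ad == 2L & !is.na(state$h_settlement))
      if (length(two_adult) > 0) {
        age_f <- year - state$p_birth[founders]
        younger <- vapply(two_adult,
                          function(h) min(age_f[hh_f == h]), numeric(1))
        born <- try_birth(younger, cfg$prob_household_birth)
        if (any(born)) {
          hh_new <- two_adult[born]
          births <- length(hh_new)
          state$p_birth <- c(state$p_birth, rep(year, births))
          state$p_hh <- c(state$p_hh, hh_new)
          state$p_founder <- c(state$p_founder, rep(FALSE, births))
        }
      }
    }
  }

  # harvest and deficit mortality
  state <- harvest_and_starve(state)
  harvest_stats <- state$last_stats

  # migration events
  members <- settlement_members(state)
  for (s in which(state$s_active & members > 0)) {
    p <- migration_probability(members[s], state$s_cap[s],
                               cfg$migration_rate, members[s])
    if (p > 0 && stats::runif(1) <= p) {
      state <- execute_migration(state, s)
      members <- settlement_members(state)
    }
  }

  # bookkeeping: activity flags and capacity growth
  members <- settlement_members(state)
  was_active <- state$s_active
  state$s_active <- members > 0
  if (!identical(was_active, state$s_active)) state$assign_dirty <- TRUE
  interval <- ceiling(cfg$yr_10)
  due <- state$s_active & (year - state$s_founded) > 0 &
    ((year - state$s_founded) %% interval == 0)
  state$s_cap[due] <- pmin(state$s_base[due],
                           state$s_cap[due] + 0.1 * state$s_base[due])

  state$last_stats <- list(
    deaths_age = deaths_age, births = births,
    deficit_deaths = harvest_stats$deficit_deaths,
    deficits = harvest_stats$deficits
  )
  state
}

#' Run the simulator and record yearly series
#'
#' Steps the model `years` times, recording population, household and
#' settlement counts, deaths by cause and the population-weighted mean
#' deficit per resource. A run whose population exceeds `hard_cap` is
#' aborted and flagged as diverged.
#'
#' @param state An `abm_state` from [init_model()].
#' @param years Number of annual timesteps.
#' @param hard_cap Abort threshold on total population (default `Inf`).
#' @return A list with `state` (final), `series` (tibble of yearly records)
#'   and `diverged` (logical).
#' @export
run_model <- function(state, years, hard_cap = Inf) {
  rows <- vector("list", years)
  diverged <- FALSE
  for (t in seq_len(years)) {
    state <- abm_step(state)
    members <- settlement_members(state)
    n_exist <- length(state$s_row)
    st <- state$last_stats
    defs <- st$deficits
    mean_def <- if (is.null(defs)) {
      stats::setNames(rep(NA_real_, 5),
                      c("maize", "forage", "fuelwood", "palm", "protein"))
    } else {
      vapply(defs, function(d) {
        m <- members[seq_along(d)]  # settlements founded after the harvest
        if (sum(m) == 0) return(0)  # this year carry no deficit
        sum(d * m) / sum(m)
      }, numeric(1))
    }
    dd <- st$deficit_deaths
    if (length(dd) == 0) {
      dd <- stats::setNames(integer(5),
                            c("maize", "forage", "fuelwood", "palm", "protein"))
    }
    rows[[t]] <- tibble::tibble(
      year = state$year,
      population = length(state$p_birth),
      households = sum(!is.na(state$h_settlement)),
      settlements_total = n_exist,
      settlements_active = sum(state$s_active),
      abandoned_frac = if (n_exist > 0) 1 - sum(state$s_active) / n_exist
        else NA_real_,
      deaths_age = st$deaths_age, births = st$births,
      deaths_maize = dd[["maize"]], deaths_forage = dd[["forage"]],
      deaths_fuelwood = dd[["fuelwood"]], deaths_palm = dd[["palm"]],
      deaths_protein = dd[["protein"]],
      deficit_maize = mean_def[["maize"]],
      deficit_fuelwood = mean_def[["fuelwood"]]
    )
    if (length(state$p_birth) > hard_cap) {
      diverged <- TRUE
      rows <- rows[seq_len(t)]
      break
    }
    if (length(state$p_birth) == 0) {
      rows <- rows[seq_len(t)]
      break
    }
  }
  list(state = state, series = dplyr::bind_rows(rows), diverged = diverged)
}

#' Settlement locations of a simulation state
#'
#' @param state An `abm_state`.
#' @param active_only Keep only settlements with at least one member
#'   household?
#' @return A site tibble (`id`, `row`, `col`).
#' @export
settlement_sites <- function(state, active_only = FALSE) {
  keep <- if (active_only) state$s_active else rep(TRUE, length(state$s_row))
  tibble::tibble(id = which(keep), row = state$s_row[keep],
                 col = state$s_col[keep])
}

#' @export
print.abm_state <- function(x, ...) {
  cat("<abm_state> year ", x$year, ": ", length(x$p_birth), " people, ",
      sum(!is.na(x$h_settlement)), " households, ",
      sum(x$s_active), "/", length(x$s_row), " settlements active\n", sep = "")
  invisible(x)
}
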