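#' Parameter space of the simulation experiments
#'
#' Ranges of the 14 continuous behavioural parameters, the 8 boolean
#' switches and the 3-option cultivation-land switch explored by the
#' experiment design.
#'
#' @return A list with `continuous` (tibble: name, min, max), `booleans`
#'   (character vector) and `case_switch` (named list of options).
#' @export
parameter_space <- function() {
  list(
    continuous = tibble::tribble(
      ~name, ~min, ~max,
      "max_set_density", 1.37, 17.96,
      "mig_dist_cost", 0, 1,
      "mig_lobe_bonus", 0, 1,
      "mig_pop_bonus", 0, 1,
      "mig_pop_cost", 0, 1,
      "mig_dist_bonus", 0, 1,
      "migration_distance", 11.38, 196.65,
      "migration_rate", 0.01, 0.20,
      "new_settlement_prob", 0.11, 0.89,
      "prob_household_birth", 0.12, 0.30,
      "protein_modifier", 0.06, 0.40,
      "settlement_base_capacity", 23.22, 492.56,
      "start_population_modifier", 0.50, 1.50,
      "yr_10", 13.52, 197.04
    ),
    booleans = c("forage_die", "forest_restrict", "fuelwood_die",
                 "intentional_agroforestry", "lobe_restrict", "maize_die",
                 "palm_die", "protein_die"),
    case_switch = list(land_for_cultivation =
                         c("Forest Only", "Savanna Only", "Forest and Savanna"))
  )
}

#' Latin hypercube sample of simulator configurations
#'
#' Maximin Latin hypercube design over the parameter space: each continuous
#' variable's range is divided into `n` equal-width strata, each hit exactly
#' once. Boolean dimensions are stratified on `[0, 1)` and thresholded at
#' 0.5; the cultivation switch splits its unit interval into equal thirds.
#' Deterministic under `seed`.
#'
#' @param space A [parameter_space()].
#' @param n Number of configurations (default 40).
#' @param seed RNG seed for the design.
#' @return A list of `n` [abm_config()] objects; the raw design matrix is
#'   attached as attribute `design`.
#' @export
lhs_sample <- function(space = parameter_space(), n = 40, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  cont <- space$continuous
  k <- nrow(cont) + length(space$booleans) + length(space$case_switch)
  set.seed(seed)
  u <- if (n == 1) matrix(stats::runif(k), 1, k) else
    lhs::maximinLHS(n, k, method = "build")
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    args <- list()
    for (j in seq_len(nrow(cont))) {
      args[[cont$name[j]]] <- cont$min[j] + u[i, j] * (cont$max[j] - cont$min[j])
    }
    for (j in seq_along(space$booleans)) {
      args[[space$booleans[j]]] <- u[i, nrow(cont) + j] < 0.5
    }
    opts <- space$case_switch$land_for_cultivation
    args$land_for_cultivation <-
      opts[pmin(length(opts), 1L + floor(u[i, k] * length(opts)))]
    args$seed <- i
    configs[[i]] <- do.call(abm_config, args)
  }
  attr(configs, "design") <- u
  configs
}

#' Run an ensemble of simulations for one configuration
#'
#' Performs `n_runs` seeded runs of `years` timesteps, records per-run
#' yearly series, and classifies the configuration as successful iff the
#' cross-run mean of total settlements falls inside
#' `success_window(nrow(ref_sites))` during at least one timestep. A
#' spatial-configuration score against the reference sites is computed at
#' the first timestep of each run whose settlement count equals the
#' reference count (when any). Runs whose population exceeds `hard_cap` are
#' aborted and flagged, and excluded from the cross-run mean.
#'
#' @param config An [abm_config()]; per-run seeds are derived from
#'   `config$seed` by a counter scheme (`seed * 1000 + run`).
#' @param landscape A [grid_landscape()].
#' @param ref_sites Reference site tibble.
#' @param n_runs Number of runs (default 50).
#' @param years Timesteps per run (default 1000).
#' @param hard_cap Population abort threshold (default 500000).
#' @param resources A [resource_params()].
#' @return A list of class `ensemble_result`: `config`, `series` (tibble
#'   with `run` column), `mean_series`, `success`, `scores` (per-run spatial
#'   scores at matched settlement count, possibly empty), `diverged`
#'   (logical per run).
#' @export
run_ensemble <- function(config, landscape, ref_sites, n_runs = 50,
                         years = 1000, hard_cap = 5e5,
                         resources = resource_params()) {
  n_ref <- nrow(ref_sites)
  win <- success_window(n_ref)
  series <- vector("list", n_runs)
  scores <- list()
  diverged <- logical(n_runs)
  for (run in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- (config$seed %% 2000L) * 1000L + run
    state <- init_model(landscape, cfg, resources = resources)
    out <- run_model(state, years, hard_cap = hard_cap)
    diverged[run] <- out$diverged
    s <- out$series
    s$run <- run
    series[[run]] <- s
    if (!out$diverged && any(s$settlements_total == n_ref) &&
        length(out$state$s_row) >= 2 && n_ref >= 2) {
      sc <- distance_score(settlement_sites(out$state), ref_sites)
      sc$run <- run
      scores[[length(scores) + 1]] <- sc
    }
  }
  all_series <- dplyr::bind_rows(series)
  ok_runs <- which(!diverged)
  mean_series <- all_series |>
    dplyr::filter(.data$run %in% ok_runs) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      population = mean(.data$population),
      settlements_total = mean(.data$settlements_total),
      settlements_active = mean(.data$settlements_active),
      abandoned_frac = mean(.data$abandoned_frac),
      n_runs = dplyr::n(), .groups = "drop")
  complete <- mean_series$n_runs == length(ok_runs) & length(ok_runs) > 0
  success <- any(complete &
                   mean_series$settlements_total >= win["low"] &
                   mean_series$settlements_total <= win["high"])
  structure(list(config = config, series = all_series,
                 mean_series = mean_series, success = success,
                 scores = dplyr::bind_rows(scores), diverged = diverged),
            class = "ensemble_result")
}

#' Aggregate ensemble results across configurations
#'
#' @param results List of [run_ensemble()] results.
#' @param ids Optional configuration ids (default sequence).
#' @return A list of tibbles: `trajectories` (per-config mean yearly
#'   series), `successes` (config id + success flag), `score_components`
#'   (per-config mean spatial-score components, long format).
#' @export
aggregate_ensembles <- function(results, ids = seq_along(results)) {
  if (length(results) == 0) stop("no results to aggregate", call. = FALSE)
  trajectories <- purrr::map2_dfr(results, ids, function(r, id) {
    dplyr::mutate(r$mean_series, config_id = id)
  })
  successes <- tibble::tibble(
    config_id = ids,
    success = purrr::map_lgl(results, "success"),
    any_diverged = purrr::map_lgl(results, ~ any(.x$diverged))
  )
  score_components <- purrr::map2_dfr(results, ids, function(r, id) {
    if (nrow(r$scores) == 0) return(NULL)
    r$scores |>
      dplyr::select(-dplyr::any_of("run")) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), mean)) |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "component",
                          values_to = "km") |>
      dplyr::mutate(config_id = id)
  })
  list(trajectories = trajectories, successes = successes,
       score_components = score_components)
}
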