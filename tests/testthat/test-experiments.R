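test_that("the design stratifies every continuous dimension", {
  space <- parameter_space()
  n <- 40
  configs <- lhs_sample(space, n = n, seed = 11)
  expect_length(configs, n)
  cont <- space$continuous
  for (j in seq_len(nrow(cont))) {
    vals <- purrr::map_dbl(configs, cont$name[j])
    u <- (vals - cont$min[j]) / (cont$max[j] - cont$min[j])
    bins <- floor(u * n) + 1
    # each of the n equal-width strata is hit exactly once
    expect_equal(sort(unique(bins)), 1:n)
  }
  # booleans and the case switch take their allowed values
  expect_true(all(purrr::map_lgl(configs,
                                 ~ is.logical(.x$maize_die))))
  expect_true(all(purrr::map_chr(configs, "land_for_cultivation") %in%
                    space$case_switch$land_for_cultivation))
})

test_that("designs are seeded: same seed repeats, different seeds differ", {
  a <- lhs_sample(n = 8, seed = 1)
  b <- lhs_sample(n = 8, seed = 1)
  c2 <- lhs_sample(n = 8, seed = 2)
  expect_identical(attr(a, "design"), attr(b, "design"))
  expect_false(identical(attr(a, "design"), attr(c2, "design")))
  one <- lhs_sample(n = 1, seed = 3)[[1]]
  expect_gte(one$migration_rate, 0.01)
  expect_lte(one$migration_rate, 0.20)
})

test_that("a small ensemble runs, records series and classifies success", {
  land <- block_landscape(50, 50, forest_cols = 25)
  ref <- grid_sites(land, n = 9, spacing = 10)
  cfg <- abm_config(seed = 5, migration_distance = 4,
                    settlement_base_capacity = 30)
  ens <- run_ensemble(cfg, land, ref, n_runs = 2, years = 50)
  expect_s3_class(ens$series, "tbl_df")
  expect_equal(sort(unique(ens$series$run)), 1:2)
  expect_true(all(c("population", "settlements_total") %in%
                    names(ens$mean_series)))
  expect_type(ens$success, "logical")
  g <- glance(ens)
  expect_equal(g$n_runs, 2)
})

test_that("a zero-birth ensemble fails and records extinction", {
  land <- block_landscape(40, 40, forest_cols = 20)
  # 25 reference sites: the success window (20-30) is out of reach for a
  # declining population that starts with 10 settlements
  ref <- site_set(tidyr::expand_grid(row = seq(4, 36, by = 8),
                                     col = seq(4, 36, by = 8)) |>
                    dplyr::mutate(id = dplyr::row_number()), land)
  cfg <- abm_config(seed = 6, prob_household_birth = 0,
                    migration_distance = 3)
  ens <- run_ensemble(cfg, land, ref, n_runs = 2, years = 120)
  expect_false(ens$success)
  last <- dplyr::slice_tail(dplyr::group_by(ens$series, run), n = 1)
  expect_true(all(last$population == 0))
})

test_that("the hard population cap aborts and flags a run", {
  land <- block_landscape(50, 50, forest_cols = 25)
  ref <- grid_sites(land, n = 4, spacing = 15)
  cfg <- abm_config(seed = 7, prob_household_birth = 0.3,
                    migration_distance = 4)
  ens <- run_ensemble(cfg, land, ref, n_runs = 1, years = 100, hard_cap = 300)
  expect_true(ens$diverged[1])
  expect_lt(max(ens$series$year), 100)
})

test_that("aggregation averages runs exactly and lists successes", {
  land <- block_landscape(40, 40, forest_cols = 20)
  ref <- grid_sites(land, n = 4, spacing = 12)
  cfgs <- list(abm_config(seed = 1, migration_distance = 3),
               abm_config(seed = 2, prob_household_birth = 0,
                          migration_distance = 3))
  results <- purrr::map(cfgs, run_ensemble, landscape = land,
                        ref_sites = ref, n_runs = 3, years = 30)
  agg <- aggregate_ensembles(results)
  expect_equal(agg$successes$success,
               purrr::map_lgl(results, "success"))
  # the mean trajectory equals a hand average over the three runs
  hand <- results[[1]]$series |>
    dplyr::group_by(year) |>
    dplyr::summarise(population = mean(population), .groups = "drop")
  got <- agg$trajectories |>
    dplyr::filter(config_id == 1) |>
    dplyr::select(year, population)
  expect_equal(got$population, hand$population)
  # permutation invariance of run order within the pooled series
  shuffled <- results[[1]]
  shuffled$series <- dplyr::arrange(shuffled$series, dplyr::desc(run), year)
  agg2 <- aggregate_ensembles(list(shuffled))
  expect_equal(agg2$trajectories$population,
               agg$trajectories$population[agg$trajectories$config_id == 1])
})
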