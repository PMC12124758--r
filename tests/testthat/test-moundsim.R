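test_that("initialisation spawns 10 settlements of two-adult households", {
  land <- block_landscape(60, 60, forest_cols = 30)
  st <- init_model(land, abm_config(seed = 5, start_population_modifier = 1))
  expect_equal(length(st$s_row), 10)
  expect_equal(sum(!is.na(st$h_settlement)), 100)
  expect_equal(length(st$p_birth), 200)
  ages <- -st$p_birth
  expect_true(all(ages >= 16 & ages <= 40))
  expect_equal(unname(st$s_cap), rep(10, 10))  # 10% of base 100
  # forest restriction puts every settlement on forest cover
  cells <- (st$s_col - 1) * 60 + st$s_row
  expect_true(all(st$cover[cells] == cc[["FOREST"]]))
  # determinism
  st2 <- init_model(land, abm_config(seed = 5, start_population_modifier = 1))
  expect_identical(st[setdiff(names(st), "config")],
                   st2[setdiff(names(st2), "config")])
})

test_that("YAML configuration maps hyphenated parameter names", {
  path <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("prob-household-birth: 0.25",
               "migration-distance: 12.5",
               "yr-10%: 50",
               "maize-die: false",
               "land-for-cultivation: Savanna Only",
               "seed: 99"), path)
  cfg <- read_abm_config(path)
  expect_equal(cfg$prob_household_birth, 0.25)
  expect_equal(cfg$migration_distance, 12.5)
  expect_equal(cfg$yr_10, 50)
  expect_false(cfg$maize_die)
  expect_equal(cfg$land_for_cultivation, "Savanna Only")
  expect_equal(cfg$seed, 99L)
  writeLines("not-a-parameter: 1", path)
  expect_error(read_abm_config(path), "unknown configuration key")
})

test_that("birth draws respect the rate and the maternal age gate", {
  set.seed(1)
  expect_false(any(try_birth(rep(30, 100), b_h = 0)))
  expect_true(all(try_birth(rep(30, 100), b_h = 1)))
  expect_false(any(try_birth(rep(50, 100), b_h = 1)))
})

test_that("mortality enforces the age cap and a null schedule spares everyone", {
  set.seed(2)
  expect_true(all(apply_mortality(rep(80, 50))))
  expect_true(all(apply_mortality(rep(95, 50))))
  zero <- mortality_schedule(Mo = rep(0, 81))
  expect_false(any(apply_mortality(rep(40, 1000), zero)))
})

test_that("a simulated cohort reproduces its schedule's survival curve", {
  # Gompertz hazard; closed-form survivorship = prod(1 - Mo) up to each age
  gomp <- mortality_schedule(Mo = pmin(1, 0.002 * exp(0.07 * 0:80)))
  set.seed(7)
  n0 <- 1e5
  alive <- rep(TRUE, n0)
  ages_checked <- c(20, 40, 60, 75)
  expected <- vapply(ages_checked,
                     function(a) prod(1 - unclass(gomp)[1:a]), numeric(1))
  got <- numeric(length(ages_checked))
  age <- 0
  for (a in seq_len(max(ages_checked))) {
    dead <- apply_mortality(rep(a - 1, sum(alive)), gomp)
    alive[which(alive)[dead]] <- FALSE
    if (a %in% ages_checked) got[match(a, ages_checked)] <- mean(alive)
  }
  # binomial error at n = 1e5: 4 sigma < 0.007
  expect_true(all(abs(got - expected) < 0.01))
})

test_that("migration probability matches brute-force evaluation with gates", {
  expect_equal(migration_probability(100, 100, 0.05, 100), 0.05)
  expect_equal(migration_probability(300, 100, 0.05, 300), 0.10)
  expect_equal(migration_probability(50, 100, 0.05, 50), 0)   # half-capacity gate
  expect_equal(migration_probability(4, 2, 0.05, 4), 0)       # five-household gate
  grid <- expand.grid(P = c(3, 5, 10, 60, 150, 400),
                      cap = c(4, 10, 50, 120),
                      Mi = c(0.01, 0.05, 0.2))
  for (i in seq_len(nrow(grid))) {
    P <- grid$P[i]; cap <- grid$cap[i]; Mi <- grid$Mi[i]
    brute <- if (P <= cap / 2 || P < 5) 0 else min(Mi * P / cap, 2 * Mi)
    expect_equal(migration_probability(P, cap, Mi, P), brute)
  }
})

test_that("location scores equal their component arithmetic", {
  w0 <- list(Pd_w = 0, D_W = 0, Di_W = 0, Pop_W = 0, Cr_W = 0)
  expect_equal(habitability_score(1, 5, 50, 100, w0, 10), 0)
  w1 <- list(Pd_w = 1, D_W = 1, Di_W = 1, Pop_W = 1, Cr_W = 1)
  # Pd=1, D=R_m, P=cap: 100 - 100 + 100 - 100 + 100
  expect_equal(habitability_score(1, 10, 100, 100, w1, 10), 100)
  wd <- list(Pd_w = 1, D_W = 1, Di_W = 0, Pop_W = 0, Cr_W = 0)
  expect_equal(suitability_score(0, 5, wd, 10), -25)
})

test_that("capacity growth steps by 10% per interval and clamps at base", {
  expect_equal(grow_capacity(200, 0, 0, 100), 20)
  expect_equal(grow_capacity(200, 0, 100, 100), 40)
  expect_equal(grow_capacity(200, 0, 2000, 100), 200)  # clamp after 10 steps
  expect_equal(grow_capacity(200, 0, 500, 100, active = FALSE,
                             current_capacity = 60), 60)
})

test_that("a 60-year run is bitwise reproducible and conserves membership", {
  land <- block_landscape(50, 50, forest_cols = 25)
  cfg <- abm_config(seed = 21, migration_distance = 4,
                    settlement_base_capacity = 40)
  a <- run_model(init_model(land, cfg), 60)
  b <- run_model(init_model(land, cfg), 60)
  expect_identical(a$series, b$series)
  expect_identical(a$state[setdiff(names(a$state), "config")],
                   b$state[setdiff(names(b$state), "config")])
  st <- a$state
  # every person belongs to a live household, every household to a settlement
  expect_true(all(!is.na(st$h_settlement[st$p_hh])))
  expect_true(all(st$h_settlement[st$p_hh] %in% seq_along(st$s_row)))
  # nobody exceeds the age cap after the mortality phase
  expect_true(all(st$year - st$p_birth <= 80))
  # active flag consistent with membership
  members <- tabulate(st$h_settlement[!is.na(st$h_settlement)],
                      nbins = length(st$s_row))
  expect_identical(st$s_active, members > 0)
})

test_that("with no births the population declines to extinction", {
  land <- block_landscape(40, 40, forest_cols = 20)
  cfg <- abm_config(seed = 3, prob_household_birth = 0,
                    migration_distance = 3)
  out <- run_model(init_model(land, cfg), 120)
  expect_true(all(diff(out$series$population) <= 0))
  expect_equal(out$series$population[nrow(out$series)], 0)
})

test_that("with ample resources and a high birth rate the population grows", {
  land <- block_landscape(80, 80, forest_cols = 40)
  cfg <- abm_config(seed = 13, prob_household_birth = 0.3,
                    migration_distance = 6)
  plenty <- resource_params(maize_yield = 1e5, fuel_yield = 1e6,
                            forage_yield = 1e6, palm_yield = 1e6,
                            protein_yield = 1e6)
  out <- run_model(init_model(land, cfg, resources = plenty), 60)
  expect_gt(out$series$population[60], out$series$population[1])
  # abundant supply: no deficit deaths recorded
  expect_equal(sum(out$series$deaths_maize) + sum(out$series$deaths_fuelwood),
               0)
})

test_that("a lethal total maize deficit wipes out a settlement within a year", {
  # forest-only cultivation on an all-savanna-but-forest-settlement landscape:
  # a single forest column hosts the settlements, zero maize land available
  land <- block_landscape(40, 40, forest_cols = 40)
  cfg <- abm_config(seed = 4, maize_die = TRUE, fuelwood_die = FALSE,
                    land_for_cultivation = "Savanna Only",
                    migration_distance = 3)
  st <- init_model(land, cfg)
  st <- abm_step(st)
  expect_equal(length(st$p_birth), 0)
  # everyone alive at the harvest died of the maize deficit (d = 1)
  expect_equal(unname(st$last_stats$deficit_deaths[["maize"]]),
               200 - st$last_stats$deaths_age + st$last_stats$births)
})

test_that("migration moves exactly the chosen group and conserves households", {
  land <- block_landscape(60, 60, forest_cols = 60)
  cfg <- abm_config(seed = 8, migration_distance = 6,
                    settlement_base_capacity = 200,
                    new_settlement_prob = 0)  # join-first; cap 20 > members
  st <- init_model(land, cfg)
  n_hh_before <- sum(!is.na(st$h_settlement))
  st2 <- execute_migration(st, 1L)
  expect_equal(sum(!is.na(st2$h_settlement)), n_hh_before)
  moved <- which(st$h_settlement == 1L & st2$h_settlement != 1L)
  expect_equal(length(moved), 5)  # minimum group size
  expect_equal(length(unique(st2$h_settlement[moved])), 1)
})

test_that("a doubly infeasible migration leaves the state unchanged", {
  land <- block_landscape(30, 30, forest_cols = 30)
  cfg <- abm_config(seed = 9, migration_distance = 1,
                    max_set_density = 0)  # founding barred, nothing to join
  st <- init_model(land, cfg)
  # isolate settlement 1: no other settlement within 1 km (probable on 30x30,
  # enforce by moving the others far would break determinism; instead bar
  # joining by zeroing every other settlement's capacity)
  st$s_cap[-1] <- 1e-9
  members <- tabulate(st$h_settlement[!is.na(st$h_settlement)],
                      nbins = length(st$s_row))
  st$s_cap[-1] <- 0.5  # below membership of 10, so no spare capacity
  st2 <- execute_migration(st, 1L)
  expect_identical(st2$h_settlement, st$h_settlement)
  expect_equal(length(st2$s_row), length(st$s_row))
})

test_that("an empty model steps without error and stays empty", {
  land <- block_landscape(30, 30, forest_cols = 15)
  st <- init_model(land, abm_config(seed = 2, start_population_modifier = 0))
  expect_equal(length(st$p_birth), 0)
  st2 <- abm_step(st)
  expect_equal(length(st2$p_birth), 0)
  expect_equal(sum(!is.na(st2$h_settlement)), 0)
})
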