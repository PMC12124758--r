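test_that("inventory volumes follow the area-ratio and per-metre rules", {
  inv <- build_inventory(mound_areas = c(2, 3), ratio = 0,
                         network_length = 0)
  expect_equal(inv$T_m, 0)
  inv2 <- build_inventory(mound_areas = 10, ratio = 100,
                          network_length = 1000, per_metre_volume = 5)
  expect_equal(inv2$T_c, 5000)
  inv3 <- build_inventory(mound_areas = 1200, ratio = 30000,
                          network_length = 0, erosion_frac = 0.02)
  expect_equal(inv3$T_m, 36e6 / 0.98, tolerance = 1e-12)
  expect_error(build_inventory(1, 1, 1, erosion_frac = 1), "erosion")
})

test_that("the load-carriage metabolic rate matches hand arithmetic", {
  expect_equal(pandolf_rate(M = 65, Q = 0, V = 0, G = 0), 97.5)
  # 1.5*65 + 2*85*(20/65)^2 + 85*(1.5*16)
  expect_equal(pandolf_rate(M = 65, Q = 20, V = 4, G = 0),
               97.5 + 2 * 85 * (20 / 65)^2 + 85 * 24)
  # doubling mu doubles only the velocity term
  base <- pandolf_rate(65, 20, 4, 10, mu = 1)
  dbl <- pandolf_rate(65, 20, 4, 10, mu = 2)
  static <- pandolf_rate(65, 20, 0, 0, mu = 1)
  expect_equal(dbl - base, base - static)
})

test_that("loaded speed solves the constant-energy equation", {
  expect_equal(loaded_speed(M = 65, Q = 0, G = 0), 5)
  # closed form at G = 0: V = sqrt((E_ref - 1.5M - 2(M+Q)(Q/M)^2)/(1.5 mu (M+Q)))
  e_ref <- pandolf_rate(65, 0, 5, 0, 1)
  v_closed <- sqrt((e_ref - 1.5 * 65 - 2 * 85 * (20 / 65)^2) / (1.5 * 85))
  expect_equal(loaded_speed(M = 65, Q = 20, G = 0), v_closed,
               tolerance = 1e-6)
  expect_equal(v_closed, 4.358, tolerance = 1e-3)
  # strictly decreasing in load and gradient
  qs <- seq(5, 60, by = 5)
  v_q <- vapply(qs, function(q) loaded_speed(65, q, 0), numeric(1))
  expect_true(all(diff(v_q) < 0))
  gs <- seq(0, 40, by = 5)
  v_g <- vapply(gs, function(g) loaded_speed(65, 20, g), numeric(1))
  expect_true(all(diff(v_g) < 0))
  expect_error(loaded_speed(M = 65, Q = 1e6, G = 0), "infeasible")
})

test_that("transport rate is volume per trip times trips per day", {
  legs <- tibble::tibble(distance = c(0.005, 0.005), speed = c(4.358, 5))
  got <- transport_rate(Q = 20, rho = 1500, legs = legs, H = 8)
  oracle <- (20 / 1500) * 8 / (0.005 / 4.358 + 0.005 / 5)
  expect_equal(got, oracle)
  expect_equal(got, 49.7, tolerance = 0.01)
  expect_equal(transport_rate(Q = 0, legs = legs), 0)
  half <- legs; half$distance <- half$distance / 2
  expect_equal(transport_rate(20, 1500, half, 8), 2 * got)
  expect_error(transport_rate(20, 1500, legs[0, ], 8), "empty")
})

test_that("daily volumes divide totals by workdays times occupation years", {
  expect_equal(annual_daily_volume(0), 0)
  expect_equal(annual_daily_volume(36792000, 18, 1000), 2044)
  expect_equal(annual_daily_volume(13125600, 18, 1000), 729.2)
})

test_that("workforce components divide daily volumes by rates", {
  w0 <- workforce(0, 0, 1, 1, 1, 1)
  expect_equal(w0$total_workforce, 0)
  w <- workforce(T_md = 2044, T_cd = 729.2, E_mx = 1.0, E_mt = 0.734,
                 E_cx = 1.0, E_ct = 33.1)
  expect_equal(w$mound_excavators, 2044)
  expect_equal(round(workforce(2044, 729.2, 0.3, 1, 0.3, 1)$mound_excavators),
               6813)
  expect_equal(w$total_workforce,
               w$canal_excavators + w$mound_excavators +
                 w$canal_transporters + w$mound_transporters)
  expect_error(workforce(1, 1, 0, 1, 1, 1), "rates")
})

test_that("population scales inversely with the workforce ratio", {
  expect_equal(population_from_workforce(5578, 1), 5578)
  expect_equal(population_from_workforce(5578, 0.5), 11156)
  expect_equal(population_from_workforce(100, 0.2), 5 * 100)
  expect_error(population_from_workforce(1, 0), "ratio")
})

test_that("workforce is degree 1 in volume and degree -1 in rates", {
  w <- workforce(2000, 700, 1.0, 0.7, 1.0, 33)
  w2 <- workforce(2 * 2000, 2 * 700, 1.0, 0.7, 1.0, 33)
  expect_equal(w2$total_workforce, 2 * w$total_workforce)
  w3 <- workforce(2000, 700, 1.0 / 2.7, 0.7 / 2.7, 1.0 / 2.7, 33 / 2.7)
  expect_equal(w3$total_workforce, 2.7 * w$total_workforce)
})

test_that("the sweep keeps transporters constant and its sums consistent", {
  inv <- build_inventory(mound_areas = 1226.31, ratio = 30000,
                         network_length = 2625120, per_metre_volume = 5)
  sw <- energetics_sweep(inv, E_mt = 0.7344, E_ct = 33.145)
  expect_equal(length(unique(sw$canal_transporters)), 1)
  expect_equal(length(unique(sw$mound_transporters)), 1)
  # population columns derive from the unrounded total
  expect_equal(sw$population_1_2, floor(sw$.unrounded_total * 2 + 0.5))
  expect_equal(sw$population_1_5, floor(sw$.unrounded_total * 5 + 0.5))
  # zero inventory gives an all-zero table
  z <- energetics_sweep(build_inventory(0, 0, 0), rates = 1)
  expect_true(all(z$total_workforce == 0))
  expect_true(all(z$population_1_3 == 0))
  pd <- person_days(sw)
  expect_true(all(pd$person_days >= 0))
  expect_equal(nrow(tidy(sw)), nrow(sw) * 9)
  expect_equal(glance(sw)$T_md, (1226.31 * 30000) / 18000)
})
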