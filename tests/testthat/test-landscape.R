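test_that("grid construction validates covers, masks and the water/elevation rule", {
  expect_error(grid_landscape(matrix(9L, 2, 2)), "unknown cover code")
  expect_error(grid_landscape(matrix(cc[["SAVANNA"]], 2, 2),
                              fertile = matrix(TRUE, 3, 3)), "shape")
  water <- matrix(cc[["WATER"]], 2, 2)
  expect_error(grid_landscape(water, elevated = matrix(TRUE, 2, 2)),
               "water cells")
  land <- savanna_grid(2)
  expect_identical(dim(land), c(2L, 2L))
  expect_equal(area_summary(land)$forest_frac_of_terrestrial, 0)
})

test_that("ASCII grid write -> read round trip reproduces per-cell values", {
  land <- block_landscape(20, 30, forest_cols = 10, water_cells = 5)
  path <- file.path(tempdir(), "rt.asc")
  write_landscape(land, path)
  back <- read_landscape(path,
                         fertile_path = file.path(tempdir(), "rt_fertile.asc"),
                         elevated_path = file.path(tempdir(), "rt_elevated.asc"))
  expect_identical(back$cover, land$cover)
  expect_identical(back$fertile, land$fertile)
  expect_identical(back$elevated, land$elevated)
  expect_error(read_landscape(file.path(tempdir(), "nope.asc")), "not found")
})

test_that("a full-size 657 x 764 raster loads with the expected dimensions", {
  cover <- matrix(cc[["SAVANNA"]], 657, 764)
  cover[, 1:300] <- cc[["FOREST"]]
  path <- file.path(tempdir(), "full.asc")
  write_ascii <- casarabe:::write_ascii_grid
  write_ascii(cover, path)
  land <- read_landscape(path)
  expect_identical(dim(land), c(657L, 764L))
})

test_that("area accounting matches direct cell counts and is additive over masks", {
  all_water <- grid_landscape(matrix(cc[["WATER"]], 100, 100))
  aw <- area_summary(all_water)
  expect_equal(aw$terrestrial_area, 0)
  expect_equal(aw$total_area, 100 * 100 / 100)

  cover <- matrix(rep(c(cc[["FOREST"]], cc[["SAVANNA"]]), c(40, 60)), 10, 10)
  land <- grid_landscape(cover)
  expect_equal(area_summary(land)$forest_frac_of_terrestrial, 0.40)

  mask <- matrix(FALSE, 10, 10); mask[1:5, ] <- TRUE
  a_in <- area_summary(land, mask)
  a_out <- area_summary(land, !mask)
  a_all <- area_summary(land)
  for (col in c("total_area", "water_area", "forest_area", "savanna_area")) {
    expect_equal(a_in[[col]] + a_out[[col]], a_all[[col]])
  }
  expect_error(area_summary(land, matrix(TRUE, 3, 3)), "shape")
})

test_that("walking mask matches disc-area oracles and is monotone in radius", {
  land <- savanna_grid(150)
  centre <- site_set(tibble::tibble(id = 1, row = 75, col = 75))
  expect_equal(sum(walking_mask(land, centre, 0)), 1)

  m7 <- walking_mask(land, centre, 7)
  expect_lt(abs(sum(m7) * 0.01 - pi * 49) / (pi * 49), 0.01)

  # two discs 20 km apart are disjoint, so areas add
  land2 <- savanna_grid(160, 360)
  two <- site_set(tibble::tibble(id = 1:2, row = c(80, 80), col = c(70, 270)))
  m2 <- walking_mask(land2, two, 7)
  expect_lt(abs(sum(m2) * 0.01 - 2 * pi * 49) / (2 * pi * 49), 0.01)

  m3 <- walking_mask(land, centre, 3)
  expect_true(all(m7[m3]))  # mask(3 km) subset of mask(7 km)

  sites <- site_set(tibble::tibble(id = 1:3, row = c(20, 75, 130),
                                   col = c(30, 75, 120)))
  rev_sites <- sites[3:1, ]; rev_sites$id <- 1:3
  expect_identical(walking_mask(land, sites, 5),
                   walking_mask(land, rev_sites, 5))
  expect_error(walking_mask(land, sites[0, ], 5), "empty")
})

test_that("site sets validate and survive CSV and GeoJSON round trips", {
  land <- savanna_grid(30)
  s <- tibble::tibble(id = 1:3, row = c(5, 10, 15), col = c(5, 10, 15))
  expect_error(site_set(rbind(s, s[1, ])), "unique")
  dup_cell <- s; dup_cell$id <- c(1, 2, 3); dup_cell$row[2] <- 5
  dup_cell$col[2] <- 5
  expect_error(site_set(dup_cell), "share a cell")
  expect_error(site_set(tibble::tibble(id = 1, row = 99, col = 1), land),
               "bounds")

  csv <- file.path(tempdir(), "sites.csv")
  gj <- file.path(tempdir(), "sites.geojson")
  write_sites(s, csv)
  write_sites(s, gj)
  expect_equal(read_sites(csv)$row, s$row)
  back <- read_sites(gj)
  expect_equal(back$row, s$row)
  expect_equal(back$col, s$col)
})
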