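# Small landscapes and site sets built in code for the test suite.

cc <- cover_codes()

# uniform savanna grid
savanna_grid <- function(n_rows, n_cols = n_rows) {
  grid_landscape(matrix(cc[["SAVANNA"]], n_rows, n_cols))
}

# landscape with a forest block in the west, savanna elsewhere, optional lake;
# forest cells are elevated, everything is fertile
block_landscape <- function(n_rows = 100, n_cols = 100,
                            forest_cols = 40, water_cells = 0) {
  cover <- matrix(cc[["SAVANNA"]], n_rows, n_cols)
  cover[, seq_len(forest_cols)] <- cc[["FOREST"]]
  if (water_cells > 0) {
    cover[seq_len(water_cells)] <- cc[["WATER"]]
  }
  grid_landscape(cover,
                 fertile = matrix(TRUE, n_rows, n_cols),
                 elevated = cover == cc[["FOREST"]])
}

# deterministic grid of sites on forest cells
grid_sites <- function(landscape, n = 5, spacing = 10) {
  d <- dim(landscape)
  rows <- seq(spacing, d[1] - spacing, length.out = ceiling(sqrt(n)))
  cols <- seq(spacing, d[2] - spacing, length.out = ceiling(sqrt(n)))
  pts <- expand.grid(row = round(rows), col = round(cols))[seq_len(n), ]
  site_set(tibble::tibble(id = seq_len(n), row = pts$row, col = pts$col),
           landscape)
}

# flood-fill connectivity check (4-neighbour) for a logical matrix
is_connected <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1) return(TRUE)
  n_rows <- nrow(mask)
  seen <- logical(length(mask))
  frontier <- idx[1]
  seen[frontier] <- TRUE
  while (length(frontier) > 0) {
    r <- ((frontier - 1) %% n_rows) + 1
    cl <- ((frontier - 1) %/% n_rows) + 1
    nb <- c(frontier[r > 1] - 1, frontier[r < n_rows] + 1,
            frontier[cl > 1] - n_rows,
            frontier[cl < ncol(mask)] + n_rows)
    nb <- unique(nb[mask[nb] & !seen[nb]])
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen[idx])
}
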