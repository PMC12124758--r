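#' Land-cover codes for gridded landscapes
#'
#' Integer codes used in the cover matrix of a [grid_landscape()]:
#' `1 = FOREST`, `2 = SAVANNA`, `3 = WATER`.
#'
#' @return Named integer vector of the three codes.
#' @export
#' @examples
#' cover_codes()
cover_codes <- function() {
  c(FOREST = 1L, SAVANNA = 2L, WATER = 3L)
}

#' Construct a gridded landscape of 1-ha patches
#'
#' The landscape is a raster of hectare-sized (100 m) square patches, each with
#' exactly one land-cover class (forest, savanna or water), a fertile flag
#' marking the late-Holocene sediment lobe, and an elevated flag marking
#' levee / non-flooding ground. Row 1 is the northern edge; row index grows
#' southward. Distances are Euclidean between cell centres on a flat grid.
#'
#' @param cover Integer matrix of land-cover codes (see [cover_codes()]).
#' @param fertile Logical matrix of the same shape; defaults to all `FALSE`.
#' @param elevated Logical matrix of the same shape; defaults to all `FALSE`.
#'   Water cells must never be elevated.
#' @return An object of class `grid_landscape`.
#' @export
#' @examples
#' land <- grid_landscape(matrix(cover_codes()[["SAVANNA"]], 4, 5))
#' dim(land)
grid_landscape <- function(cover, fertile = NULL, elevated = NULL) {
  if (!is.matrix(cover)) stop("`cover` must be a matrix", call. = FALSE)
  storage.mode(cover) <- "integer"
  bad <- setdiff(unique(as.vector(cover)), unname(cover_codes()))
  if (length(bad) > 0) {
    stop("unknown cover code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(fertile)) fertile <- matrix(FALSE, nrow(cover), ncol(cover))
  if (is.null(elevated)) elevated <- matrix(FALSE, nrow(cover), ncol(cover))
  for (nm in c("fertile", "elevated")) {
    m <- get(nm)
    if (!is.matrix(m) || !identical(dim(m), dim(cover))) {
      stop("`", nm, "` must be a logical matrix matching `cover`'s shape",
           call. = FALSE)
    }
    if (anyNA(m)) stop("`", nm, "` must be defined for every cell", call. = FALSE)
  }
  storage.mode(fertile) <- "logical"
  storage.mode(elevated) <- "logical"
  if (any(elevated & cover == cover_codes()[["WATER"]])) {
    stop("water cells cannot be marked elevated", call. = FALSE)
  }
  structure(
    list(cover = cover, fertile = fertile, elevated = elevated, cell_m = 100),
    class = "grid_landscape"
  )
}

#' @export
dim.grid_landscape <- function(x) dim(x$cover)

#' @export
print.grid_landscape <- function(x, ...) {
  n <- length(x$cover)
  cc <- cover_codes()
  cat("<grid_landscape> ", nrow(x$cover), " x ", ncol(x$cover),
      " cells (1 ha each)\n", sep = "")
  cat(sprintf("  forest %.1f%%  savanna %.1f%%  water %.1f%%  fertile %.1f%%  elevated %.1f%%\n",
              100 * mean(x$cover == cc[["FOREST"]]),
              100 * mean(x$cover == cc[["SAVANNA"]]),
              100 * mean(x$cover == cc[["WATER"]]),
              100 * mean(x$fertile), 100 * mean(x$elevated)))
  invisible(x)
}

#' Validate a table of settlement / mound sites
#'
#' A site set is a tibble with columns `id`, `row`, `col`: one cell per site,
#' unique ids, coordinates inside the grid when a landscape is supplied, and
#' no two sites sharing a cell.
#'
#' @param x Data frame with columns `id`, `row`, `col`.
#' @param landscape Optional [grid_landscape()] used to bound-check coordinates.
#' @return A validated tibble of sites.
#' @export
site_set <- function(x, landscape = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("id", "row", "col")
  if (!all(need %in% names(x))) {
    stop("site set needs columns id, row, col", call. = FALSE)
  }
  x$row <- as.integer(x$row)
  x$col <- as.integer(x$col)
  if (anyDuplicated(x$id) > 0) stop("site ids must be unique", call. = FALSE)
  if (anyDuplicated(x[c("row", "col")]) > 0) {
    stop("no two sites may share a cell", call. = FALSE)
  }
  if (!is.null(landscape)) {
    d <- dim(landscape)
    if (any(x$row < 1 | x$row > d[1] | x$col < 1 | x$col > d[2])) {
      stop("site coordinates outside grid bounds", call. = FALSE)
    }
  }
  x[need]
}

# ---- ESRI ASCII grid I/O -----------------------------------------------------
# No raster package is available, and the dialect is a 6-line header plus a
# whitespace-separated matrix (row 1 = northern edge), so it is parsed directly.

read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows)) {
    stop("not an ESRI ASCII grid (missing ncols/nrows header): ", path,
         call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
}

write_ascii_grid <- function(m, path, cellsize = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", cellsize),
    "NODATA_value -9999"
  ), con)
  apply_rows <- apply(m, 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

#' Read a gridded landscape from ESRI ASCII grids
#'
#' Reads a single-band integer cover raster (codes per [cover_codes()]) plus
#' optional sidecar 0/1 rasters for the fertile and elevated masks. All bands
#' must share the same dimensions.
#'
#' @param path Path to the cover raster (ESRI ASCII grid).
#' @param fertile_path,elevated_path Optional paths to 0/1 mask rasters.
#' @return A [grid_landscape()].
#' @export
read_landscape <- function(path, fertile_path = NULL, elevated_path = NULL) {
  cover <- read_ascii_grid(path)
  fertile <- elevated <- NULL
  if (!is.null(fertile_path)) {
    fertile <- read_ascii_grid(fertile_path) != 0
    if (!identical(dim(fertile), dim(cover))) {
      stop("fertile band dimensions do not match cover", call. = FALSE)
    }
  }
  if (!is.null(elevated_path)) {
    elevated <- read_ascii_grid(elevated_path) != 0
    if (!identical(dim(elevated), dim(cover))) {
      stop("elevated band dimensions do not match cover", call. = FALSE)
    }
  }
  grid_landscape(cover, fertile, elevated)
}

#' Write a gridded landscape as ESRI ASCII grids
#'
#' Writes the cover band to `path` and, unless masks are all-`FALSE`, sidecar
#' `*_fertile.asc` / `*_elevated.asc` grids next to it.
#'
#' @param landscape A [grid_landscape()].
#' @param path Output path for the cover raster.
#' @param masks Write the fertile/elevated sidecar grids too?
#' @return Invisibly, a character vector of the files written.
#' @export
write_landscape <- function(landscape, path, masks = TRUE) {
  files <- write_ascii_grid(landscape$cover, path)
  if (masks) {
    stem <- sub("\\.asc$", "", path)
    files <- c(files,
               write_ascii_grid(landscape$fertile * 1L,
                                paste0(stem, "_fertile.asc")),
               write_ascii_grid(landscape$elevated * 1L,
                                paste0(stem, "_elevated.asc")))
  }
  invisible(files)
}

#' Read a site set from CSV or GeoJSON
#'
#' CSV files need columns `id,row,col`. GeoJSON point features are mapped to
#' grid cells via their `row`/`col` properties.
#'
#' @param path Path to a `.csv` or `.geojson`/`.json` file.
#' @param landscape Optional [grid_landscape()] for bound checks.
#' @return A validated site tibble.
#' @export
read_sites <- function(path, landscape = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    df <- tibble::tibble(
      id = purrr::map_chr(feats, ~ as.character(.x$properties$id)),
      row = purrr::map_int(feats, ~ as.integer(.x$properties$row)),
      col = purrr::map_int(feats, ~ as.integer(.x$properties$col))
    )
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
  }
  site_set(df, landscape)
}

#' Write a site set to CSV or GeoJSON
#'
#' @param sites Site tibble (`id`, `row`, `col`).
#' @param path Output path; `.geojson` selects GeoJSON points (cell-centre
#'   coordinates in km, y increasing southward), anything else CSV.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(sites, path) {
  sites <- site_set(sites)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- purrr::pmap(sites, function(id, row, col) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c((col - 0.5) * 0.1, (row - 0.5) * 0.1)),
           properties = list(id = id, row = row, col = col))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(sites, path)
  }
  invisible(path)
}

#' Summarise landscape areas in square kilometres
#'
#' Counts cells (1 ha each, so km2 = count / 100) overall and per cover class,
#' optionally restricted to a mask such as the output of [walking_mask()].
#' Water + terrestrial = total and forest + savanna = terrestrial by
#' construction.
#'
#' @param landscape A [grid_landscape()].
#' @param mask Optional logical matrix matching the grid shape.
#' @return One-row tibble: `total_area`, `water_area`, `terrestrial_area`,
#'   `forest_area`, `savanna_area` (km2) and `forest_frac_of_terrestrial`.
#' @export
#' @examples
#' land <- grid_landscape(matrix(rep(c(1L, 2L), c(40, 60)), 10, 10))
#' area_summary(land)$forest_frac_of_terrestrial  # 0.4
area_summary <- function(landscape, mask = NULL) {
  cc <- cover_codes()
  cov <- landscape$cover
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(cov))) {
      stop("mask shape does not match landscape", call. = FALSE)
    }
    cov <- cov[mask]
  }
  n_water <- sum(cov == cc[["WATER"]])
  n_forest <- sum(cov == cc[["FOREST"]])
  n_savanna <- sum(cov == cc[["SAVANNA"]])
  n_terr <- n_forest + n_savanna
  tibble::tibble(
    total_area = (n_water + n_terr) / 100,
    water_area = n_water / 100,
    terrestrial_area = n_terr / 100,
    forest_area = n_forest / 100,
    savanna_area = n_savanna / 100,
    forest_frac_of_terrestrial = if (n_terr > 0) n_forest / n_terr else NA_real_
  )
}

#' Cells within daily walking distance of any site
#'
#' Marks every cell whose centre lies within `radius` km (Euclidean, flat
#' grid, 100 m cells) of the centre of any site's cell. The default 7 km is
#' the daily walking distance recorded for modern Amazonian indigenous groups.
#'
#' @param landscape A [grid_landscape()].
#' @param sites Site tibble (`id`, `row`, `col`); must be non-empty.
#' @param radius Radius in km (>= 0).
#' @return Logical matrix of the grid's shape.
#' @export
walking_mask <- function(landscape, sites, radius = 7) {
  sites <- site_set(sites, landscape)
  if (nrow(sites) == 0) stop("site set is empty", call. = FALSE)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  d <- dim(landscape)
  mask <- matrix(FALSE, d[1], d[2])
  r_cells <- radius / 0.1  # cell size 100 m
  span <- floor(r_cells)
  for (i in seq_len(nrow(sites))) {
    r0 <- sites$row[i]; c0 <- sites$col[i]
    rr <- max(1, r0 - span):min(d[1], r0 + span)
    cs <- max(1, c0 - span):min(d[2], c0 + span)
    sub <- outer((rr - r0)^2, (cs - c0)^2, `+`) <= r_cells^2
    mask[rr, cs] <- mask[rr, cs] | sub
  }
  mask
}
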