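site_coords_km <- function(sites) {
  sites <- site_set(sites)
  # cell centres; x east-west from columns, y north-south from rows
  cbind(x = (sites$col - 0.5) * 0.1, y = (sites$row - 0.5) * 0.1)
}

#' Point-pattern summary statistics of a site set
#'
#' Statistics (all in km, between cell centres): mean and SD of the
#' nearest-neighbour distance; mean x (east-west) and y (north-south,
#' increasing southward) position; mean and SD of the distance to a centroid
#' (the set's own unless `centroid` is supplied, e.g. the reference mound
#' centroid); and the SD across sites of each site's mean distance to all
#' others.
#'
#' @param sites Site tibble with at least 2 sites.
#' @param centroid Optional `c(x, y)` in km overriding the set's own mean
#'   position for the distance-to-centroid statistics.
#' @return One-row tibble: `nn_mean`, `nn_sd`, `x_mean`, `y_mean`,
#'   `centroid_dist_mean`, `centroid_dist_sd`, `mean_dist_sd`.
#' @export
#' @examples
#' sq <- tibble::tibble(id = 1:4, row = c(5, 5, 15, 15), col = c(5, 15, 5, 15))
#' point_stats(sq)
point_stats <- function(sites, centroid = NULL) {
  xy <- site_coords_km(sites)
  n <- nrow(xy)
  if (n < 2) stop("point_stats needs at least 2 sites", call. = FALSE)
  dm <- as.matrix(stats::dist(xy))
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  diag(dm) <- 0
  mean_to_others <- rowSums(dm) / (n - 1)
  if (is.null(centroid)) centroid <- colMeans(xy)
  cd <- sqrt((xy[, 1] - centroid[1])^2 + (xy[, 2] - centroid[2])^2)
  tibble::tibble(
    nn_mean = mean(nn), nn_sd = stats::sd(nn),
    x_mean = mean(xy[, 1]), y_mean = mean(xy[, 2]),
    centroid_dist_mean = mean(cd), centroid_dist_sd = stats::sd(cd),
    mean_dist_sd = stats::sd(mean_to_others)
  )
}

#' Spatial-configuration distance between two site sets
#'
#' Each component is the absolute difference (km) of a point-pattern
#' statistic between a simulated and a reference site set; the total is
#' their unweighted sum. The distance-to-centroid statistics of both sets
#' use the REFERENCE set's mean position. Components: `distMinDistMean`,
#' `distMinDistSD` (nearest neighbour), `distXcorMean`, `distYcorMean`
#' (centroid offsets), `distxycorMean`, `distxycorSD` (distance to the
#' reference centroid), `distMeandistSD` (SD of per-site mean pairwise
#' distance).
#'
#' @param sim,ref Site tibbles, each with at least 2 sites.
#' @param weights Optional named numeric vector reweighting the seven
#'   components in the total (default all 1).
#' @return One-row tibble of class `spatial_score` with the components and
#'   `total`.
#' @export
distance_score <- function(sim, ref, weights = NULL) {
  ref_stats <- point_stats(ref)
  ref_centroid <- c(ref_stats$x_mean, ref_stats$y_mean)
  ref_c <- point_stats(ref, centroid = ref_centroid)
  sim_c <- point_stats(sim, centroid = ref_centroid)
  comp <- c(
    distMinDistMean = abs(sim_c$nn_mean - ref_c$nn_mean),
    distMinDistSD = abs(sim_c$nn_sd - ref_c$nn_sd),
    distXcorMean = abs(sim_c$x_mean - ref_c$x_mean),
    distYcorMean = abs(sim_c$y_mean - ref_c$y_mean),
    distxycorMean = abs(sim_c$centroid_dist_mean - ref_c$centroid_dist_mean),
    distxycorSD = abs(sim_c$centroid_dist_sd - ref_c$centroid_dist_sd),
    distMeandistSD = abs(sim_c$mean_dist_sd - ref_c$mean_dist_sd)
  )
  if (is.null(weights)) weights <- stats::setNames(rep(1, 7), names(comp))
  out <- tibble::as_tibble(as.list(comp))
  out$total <- sum(comp * weights[names(comp)])
  structure(out, class = c("spatial_score", class(out)))
}

#' Settlement-count success window
#'
#' The band of settlement counts considered to match a reference site set:
#' `round(n_ref * (1 - tol))` to `round(n_ref * (1 + tol))` with half-up
#' rounding. With the 119 reference mounds and 20% tolerance this is
#' 95-143 settlements.
#'
#' @param n_ref Reference site count (>= 1).
#' @param tol Tolerance as a proportion (default 0.2).
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' success_window(119)  # 95, 143
success_window <- function(n_ref, tol = 0.2) {
  if (n_ref < 1) stop("n_ref must be >= 1", call. = FALSE)
  c(low = floor(n_ref * (1 - tol) + 0.5), high = floor(n_ref * (1 + tol) + 0.5))
}
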