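#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an energetics sweep into long format
#'
#' @param x An [energetics_sweep()] result.
#' @param ... Unused.
#' @return A tibble with one row per (excavation rate, role) head count.
#' @export
tidy.energetics_sweep <- function(x, ...) {
  x |>
    dplyr::select(-dplyr::starts_with(".unrounded")) |>
    tidyr::pivot_longer(-"excavation_rate", names_to = "quantity",
                        values_to = "persons")
}

#' @rdname tidy.energetics_sweep
#' @return For `glance`: one row with daily volumes, transport rates and the
#'   workforce/population extremes of the sweep.
#' @export
glance.energetics_sweep <- function(x, ...) {
  dv <- attr(x, "daily_volumes")
  tr <- attr(x, "transport_rates")
  pop_cols <- grep("^population_", names(x), value = TRUE)
  tibble::tibble(
    T_md = dv[["T_md"]], T_cd = dv[["T_cd"]],
    E_mt = tr[["E_mt"]], E_ct = tr[["E_ct"]],
    workforce_min = min(x$total_workforce),
    workforce_max = max(x$total_workforce),
    population_min = min(as.matrix(x[pop_cols])),
    population_max = max(as.matrix(x[pop_cols]))
  )
}

#' Tidy a spatial score into component rows
#'
#' @param x A [distance_score()] result.
#' @param ... Unused.
#' @return A tibble with `component` and `km` columns (total excluded).
#' @export
tidy.spatial_score <- function(x, ...) {
  x |>
    dplyr::select(-"total", -dplyr::any_of("run")) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "component",
                        values_to = "km")
}

#' @rdname tidy.spatial_score
#' @export
glance.spatial_score <- function(x, ...) {
  tibble::tibble(total = x$total, n_components = 7L)
}

#' Tidy an ensemble result into its mean yearly series
#'
#' @param x A [run_ensemble()] result.
#' @param ... Unused.
#' @return The cross-run mean yearly series tibble.
#' @export
tidy.ensemble_result <- function(x, ...) x$mean_series

#' @rdname tidy.ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  tibble::tibble(
    success = x$success,
    n_runs = length(x$diverged),
    n_diverged = sum(x$diverged),
    peak_mean_population = max(x$mean_series$population),
    peak_mean_settlements = max(x$mean_series$settlements_total)
  )
}
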