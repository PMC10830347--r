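#' Cumulative (year-on-year) adequacy series
#'
#' For each year `y` in `years`, recomputes the adequacy metrics on all
#' checklists with `year <= y` — how the metrics change as data accumulate.
#' MIC and TRC are monotone non-decreasing along this series (records only
#' accumulate); CSB is not constrained and can worsen as effort concentrates.
#'
#' @param table A filtered [checklist_table()].
#' @param ranges Range table.
#' @param grid A [grid_spec()].
#' @param years Integer vector of years (default 1980:2022).
#' @param h_fun Sampling-bias divergence; see [h_total_variation()].
#' @return A tibble of series points: `year`, `species`, `mic`, `trc`, `csb`,
#'   `n_range_cells`, `n_checklists_in_range`.
#' @export
cumulative_series <- function(table, ranges, grid, years = 1980:2022,
                              h_fun = h_total_variation) {
  stopifnot(length(years) > 0L)
  series_by_year(table, ranges, grid, years, h_fun,
                 function(cl_year, y) cl_year <= y)
}

#' Annual (year-by-year) adequacy series
#'
#' For each year, recomputes the adequacy metrics on that year's checklists
#' alone.
#'
#' @inheritParams cumulative_series
#' @return A tibble of series points (as [cumulative_series()]).
#' @export
annual_series <- function(table, ranges, grid, years = 1980:2022,
                          h_fun = h_total_variation) {
  stopifnot(length(years) > 0L)
  series_by_year(table, ranges, grid, years, h_fun,
                 function(cl_year, y) cl_year == y)
}

series_by_year <- function(table, ranges, grid, years, h_fun, keep) {
  purrr::map_dfr(sort(unique(as.integer(years))), function(y) {
    sel <- keep(table$checklists$year, y)
    cl <- table$checklists[sel, ]
    obs <- table$observations[table$observations$checklist_id %in%
                                cl$checklist_id, ]
    sub <- checklist_table(cl, obs)
    compute_adequacy(sub, ranges, grid, h_fun = h_fun) |>
      dplyr::mutate(year = y, .before = 1)
  })
}

#' Cross-species percentile summaries of a series
#'
#' Per year and metric: the median and the 5th/95th percentiles (linear
#' interpolation between order statistics) over species with a defined value.
#' Species-years with missing CSB are excluded from that year's CSB summary;
#' `n_species_defined` records how many species contributed.
#'
#' @param points Series points from [cumulative_series()] or
#'   [annual_series()].
#' @return A tibble: `year`, `metric`, `median`, `p05`, `p95`,
#'   `n_species_defined`.
#' @export
summarize_series <- function(points) {
  points |>
    tidyr::pivot_longer(cols = c("mic", "trc", "csb"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$year, .data$metric) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      p05 = stats::quantile(.data$value, 0.05, type = 7, names = FALSE),
      p95 = stats::quantile(.data$value, 0.95, type = 7, names = FALSE),
      n_species_defined = dplyr::n(),
      .groups = "drop")
}
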