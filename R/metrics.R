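#' Per-cell species inventories
#'
#' For every grid cell belonging to at least one species' range, tallies the
#' *expected* richness (species whose gridded range contains the cell, from
#' the stacked range maps), the *observed* richness (species with at least one
#' surviving record in the cell), the number of surviving checklists in the
#' cell, and the cell's inventory completeness
#' `ic = observed richness / expected richness`. Cells in no range are
#' omitted (inventory completeness is undefined there). Unsurveyed range
#' cells are present with `ic = 0`.
#'
#' @param table A filtered [checklist_table()].
#' @param ranges Range table (`species`, `col`, `row`, `cell`); must be
#'   non-empty.
#' @param grid A [grid_spec()].
#' @return An object of class `cell_inventories`: a list with
#'   * `cells`: tibble (`cell`, `col`, `row`, `n_expected`, `n_observed`,
#'     `n_checklists`, `ic`), one row per range cell;
#'   * `detections`: tibble (`species`, `cell`) of distinct species-in-cell
#'     records.
#' @export
build_inventories <- function(table, ranges, grid) {
  if (nrow(ranges) == 0L) {
    rlang::abort("Range table is empty.", class = "adequacy_schema_error")
  }
  cl_cells <- add_cell(table$checklists, grid)
  detections <- table$observations |>
    dplyr::inner_join(cl_cells[, c("checklist_id", "cell")],
                      by = "checklist_id") |>
    dplyr::distinct(.data$species, .data$cell)
  effort <- cl_cells |> dplyr::count(.data$cell, name = "n_checklists")
  expected <- ranges |>
    dplyr::count(.data$cell, .data$col, .data$row, name = "n_expected")
  observed <- detections |> dplyr::count(.data$cell, name = "n_observed")
  cells <- expected |>
    dplyr::left_join(observed, by = "cell") |>
    dplyr::left_join(effort, by = "cell") |>
    dplyr::mutate(
      n_observed = dplyr::coalesce(.data$n_observed, 0L),
      n_checklists = dplyr::coalesce(.data$n_checklists, 0L),
      ic = .data$n_observed / .data$n_expected) |>
    dplyr::select("cell", "col", "row", "n_expected", "n_observed",
                  "n_checklists", "ic") |>
    dplyr::arrange(.data$cell)
  structure(list(cells = cells, detections = detections),
            class = "cell_inventories")
}

#' @export
print.cell_inventories <- function(x, ...) {
  cat(sprintf("<cell_inventories> %d range cells, %d species-cell detections\n",
              nrow(x$cells), nrow(x$detections)))
  invisible(x)
}

#' Inventory completeness of a cell
#'
#' The proportion of the expected diversity (species mapped in the cell) that
#' has been observed there.
#'
#' @param n_observed,n_expected Integer vectors; `n_expected` must be >= 1
#'   (cells expected to hold no species have undefined completeness and never
#'   enter the metric).
#' @return Numeric vector of completeness fractions in `[0, 1]`.
#' @export
inventory_completeness <- function(n_observed, n_expected) {
  if (any(n_expected < 1)) {
    rlang::abort("Inventory completeness is undefined for cells with no expected species.",
                 class = "adequacy_undefined_cell_error")
  }
  n_observed / n_expected
}

#' Total-variation divergence between observed effort and a uniform null
#'
#' The default sampling-bias statistic `H`: with `p` the observed share of
#' checklists in each of the `n` range cells and `e = 1/n` the uniform null,
#' `H = 0.5 * sum(|p - e|)` — the proportional difference between the two
#' distributions, bounded in `[0, 1)`. `1 - H` equals the Schoener-type
#' proportional similarity `sum(pmin(p, e))`.
#'
#' Any replacement must map a vector of per-cell checklist counts (length =
#' number of range cells, sum > 0) to a divergence in `[0, 1)` with 0 at the
#' uniform distribution; pass it as `h_fun` to [compute_adequacy()].
#'
#' @param counts Integer vector of checklists per range cell (sum > 0).
#' @return The divergence `H` in `[0, 1)`.
#' @export
h_total_variation <- function(counts) {
  n <- length(counts)
  p <- counts / sum(counts)
  sum(abs(p - 1 / n)) / 2
}

#' Per-species adequacy metrics
#'
#' Computes, for every species in `ranges`, the three data-adequacy metrics:
#'
#' * **MIC** (mean inventory completeness): the unweighted mean of inventory
#'   completeness over all cells of the species' gridded range. Unsurveyed
#'   range cells contribute 0 — an unsurveyed range must not look complete.
#' * **TRC** (total range completeness): the proportion of range cells with
#'   at least one record of the species.
#' * **CSB** (checklist spatial bias, `1 - H`): one minus the divergence
#'   between the observed distribution of checklists over the range cells and
#'   a uniform null. Higher = more even effort. `NA` when the species has no
#'   checklists anywhere in its range (the statistic is undefined, not zero).
#'
#' @param table A filtered [checklist_table()].
#' @param ranges Range table (`species`, `col`, `row`, `cell`).
#' @param grid A [grid_spec()].
#' @param h_fun Sampling-bias divergence; see [h_total_variation()].
#' @return A tibble with one row per species: `species`, `mic`, `trc`, `csb`,
#'   `n_range_cells`, `n_checklists_in_range`.
#' @examples
#' cfg <- world_config(seed = 1)
#' sim <- simulate_world(cfg)
#' compute_adequacy(sim$table, sim$world$ranges, cfg$grid)
#' @export
compute_adequacy <- function(table, ranges, grid, h_fun = h_total_variation) {
  inv <- build_inventories(table, ranges, grid)
  per_cell <- ranges |>
    dplyr::left_join(inv$cells[, c("cell", "ic", "n_checklists")], by = "cell") |>
    dplyr::left_join(dplyr::mutate(inv$detections, detected = TRUE),
                     by = c("species", "cell")) |>
    dplyr::mutate(detected = dplyr::coalesce(.data$detected, FALSE))
  per_cell |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      mic = mean(.data$ic),
      trc = mean(.data$detected),
      csb = if (sum(.data$n_checklists) == 0L) NA_real_
            else 1 - h_fun(.data$n_checklists),
      n_range_cells = dplyr::n(),
      n_checklists_in_range = sum(.data$n_checklists),
      .groups = "drop") |>
    dplyr::arrange(.data$species)
}

#' Mean inventory completeness of one species
#'
#' @param species Species code.
#' @param ranges Range table.
#' @param inventories Output of [build_inventories()].
#' @return A single fraction in `[0, 1]`.
#' @export
mic <- function(species, ranges, inventories) {
  cells <- ranges$cell[ranges$species == species]
  stopifnot(length(cells) > 0L)
  ic <- inventories$cells$ic[match(cells, inventories$cells$cell)]
  mean(ic)
}

#' Total range completeness of one species
#'
#' @inheritParams mic
#' @return A single fraction in `[0, 1]`.
#' @export
trc <- function(species, ranges, inventories) {
  cells <- ranges$cell[ranges$species == species]
  stopifnot(length(cells) > 0L)
  det <- inventories$detections$cell[inventories$detections$species == species]
  mean(cells %in% det)
}

#' Checklist spatial bias of one species
#'
#' @inheritParams mic
#' @param h_fun Sampling-bias divergence; see [h_total_variation()].
#' @return `1 - H`, or `NA` if the species has no in-range checklists.
#' @export
csb <- function(species, ranges, inventories, h_fun = h_total_variation) {
  cells <- ranges$cell[ranges$species == species]
  stopifnot(length(cells) > 0L)
  counts <- inventories$cells$n_checklists[match(cells, inventories$cells$cell)]
  if (sum(counts) == 0L) return(NA_real_)
  1 - h_fun(counts)
}

#' Write an adequacy table to CSV
#'
#' @param adequacy Output of [compute_adequacy()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adequacy <- function(adequacy, path) {
  readr::write_csv(adequacy, path)
  invisible(path)
}
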