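#' Column mapping for occurrence CSV files
#'
#' eBird-style and Birdata-style exports use different headers; a column map
#' names, for each field the pipeline needs, the column that holds it in a
#' given file. Fields `group_id`, `source` and `count` are optional in the
#' file (pass `NULL` to mark them absent).
#'
#' @param checklist_id,species,lon,lat,year,complete Required column names.
#' @param count,group_id,source Optional column names (`NULL` if the file has
#'   no such column).
#' @return A named list usable as the `col_map` argument of
#'   [read_occurrences()].
#' @export
occurrence_column_map <- function(checklist_id = "checklist_id",
                                  species = "species",
                                  lon = "lon", lat = "lat",
                                  year = "year", complete = "complete",
                                  count = "count", group_id = "group_id",
                                  source = "source") {
  list(checklist_id = checklist_id, species = species, lon = lon, lat = lat,
       year = year, complete = complete, count = count, group_id = group_id,
       source = source)
}

#' Construct a checklist table
#'
#' The central container for survey data: one row per checklist (the unit of
#' sampling effort) in `$checklists`, one row per species observation in
#' `$observations`, and per-stage filtering counts in `$provenance`.
#'
#' @param checklists Tibble with columns `checklist_id`, `lon`, `lat`, `year`,
#'   `complete`, `group_id`, `source`.
#' @param observations Tibble with columns `checklist_id`, `species`, `count`
#'   (`NA` for present-only records).
#' @param provenance Tibble of per-stage removal counts
#'   (`stage`, `checklists_removed`, `observations_removed`).
#' @return An object of class `checklist_table`.
#' @export
checklist_table <- function(checklists, observations,
                            provenance = empty_provenance()) {
  checklists <- tibble::as_tibble(checklists)
  observations <- tibble::as_tibble(observations)
  stopifnot(all(c("checklist_id", "lon", "lat", "year", "complete")
                %in% names(checklists)),
            all(c("checklist_id", "species") %in% names(observations)))
  if (!"group_id" %in% names(checklists)) checklists$group_id <- NA_character_
  if (!"source" %in% names(checklists)) checklists$source <- NA_character_
  if (!"count" %in% names(observations)) observations$count <- NA_real_
  orphans <- setdiff(observations$checklist_id, checklists$checklist_id)
  if (length(orphans) > 0L) {
    rlang::abort(sprintf(
      "%d observation(s) reference unknown checklist ids (e.g. %s).",
      length(orphans), orphans[1]), class = "adequacy_schema_error")
  }
  structure(list(checklists = checklists, observations = observations,
                 provenance = tibble::as_tibble(provenance)),
            class = "checklist_table")
}

empty_provenance <- function() {
  tibble::tibble(stage = character(), checklists_removed = integer(),
                 observations_removed = integer())
}

add_provenance <- function(prov, stage, n_checklists, n_obs) {
  dplyr::bind_rows(prov, tibble::tibble(
    stage = stage, checklists_removed = as.integer(n_checklists),
    observations_removed = as.integer(n_obs)))
}

#' @export
print.checklist_table <- function(x, ...) {
  cat(sprintf("<checklist_table> %d checklists, %d observations, %d species\n",
              nrow(x$checklists), nrow(x$observations),
              dplyr::n_distinct(x$observations$species)))
  if (nrow(x$provenance) > 0L) {
    cat("filtering provenance:\n")
    print(x$provenance)
  }
  invisible(x)
}

#' Read checklist occurrence records from CSV
#'
#' Reads one observation per row and groups rows into checklists by
#' `checklist_id`. Counts that fail to parse as numbers (the usual `"X"`
#' present-only marker) are kept as present-only records (`count = NA`).
#' Rows with an unparseable required field are skipped and counted in the
#' provenance under stage `"unparseable"`.
#'
#' @param path Path to the occurrence CSV.
#' @param col_map A column mapping from [occurrence_column_map()].
#' @return A raw (unfiltered) [checklist_table()].
#' @export
read_occurrences <- function(path, col_map = occurrence_column_map()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    rlang::warn(sprintf("Occurrence file '%s' is empty.", path))
  }
  required <- c("checklist_id", "species", "lon", "lat", "year", "complete")
  mapped <- purrr::compact(col_map)
  missing_cols <- setdiff(unlist(mapped[required]), names(raw))
  if (nrow(raw) > 0L && length(missing_cols) > 0L) {
    rlang::abort(sprintf("Occurrence CSV lacks mapped column(s): %s.",
                         paste(missing_cols, collapse = ", ")),
                 class = "adequacy_schema_error")
  }
  get_col <- function(field) {
    nm <- col_map[[field]]
    if (is.null(nm) || !nm %in% names(raw)) rep(NA_character_, nrow(raw))
    else raw[[nm]]
  }
  df <- tibble::tibble(
    checklist_id = get_col("checklist_id"),
    species = get_col("species"),
    count_raw = get_col("count"),
    lon = suppressWarnings(as.numeric(get_col("lon"))),
    lat = suppressWarnings(as.numeric(get_col("lat"))),
    year = suppressWarnings(as.integer(get_col("year"))),
    complete_raw = tolower(get_col("complete")),
    group_id = get_col("group_id"),
    source = get_col("source"))
  df$complete <- dplyr::case_when(
    df$complete_raw %in% c("true", "t", "1", "yes") ~ TRUE,
    df$complete_raw %in% c("false", "f", "0", "no") ~ FALSE,
    TRUE ~ NA)
  ok <- !is.na(df$checklist_id) & !is.na(df$species) & !is.na(df$lon) &
    !is.na(df$lat) & !is.na(df$year) & !is.na(df$complete)
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    rlang::warn(sprintf("Skipped %d unparseable row(s) in '%s'.", n_bad, path))
  }
  df <- df[ok, ]
  # numeric counts must be >= 1; anything else is a present-only marker
  count <- suppressWarnings(as.numeric(df$count_raw))
  count[!is.na(count) & count < 1] <- NA_real_
  observations <- tibble::tibble(checklist_id = df$checklist_id,
                                 species = df$species, count = count)
  checklists <- df |>
    dplyr::distinct(.data$checklist_id, .data$lon, .data$lat, .data$year,
                    .data$complete, .data$group_id, .data$source)
  dup <- checklists |> dplyr::count(.data$checklist_id) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    rlang::abort(sprintf(
      "Checklist id(s) with conflicting header fields: %s.",
      paste(head(dup$checklist_id, 3), collapse = ", ")),
      class = "adequacy_schema_error")
  }
  prov <- add_provenance(empty_provenance(), "unparseable", 0L, n_bad)
  checklist_table(checklists, observations, prov)
}

#' Filter checklists: complete lists, in-extent, shared-list deduplication
#'
#' Applies the checklist-level filters: drops non-complete checklists
#' (incidental observations), drops checklists outside the grid extent, and
#' removes duplicate copies of shared checklists (for each `group_id`, the
#' checklist with the lexicographically smallest `checklist_id` is kept).
#' No effort-variable filtering (duration, distance) is performed.
#'
#' @param table A [checklist_table()] (raw or already filtered; the operation
#'   is idempotent).
#' @param grid A [grid_spec()].
#' @return A filtered [checklist_table()] with updated provenance.
#' @export
filter_checklists <- function(table, grid) {
  cl <- table$checklists
  obs <- table$observations
  prov <- table$provenance

  drop_stage <- function(cl, obs, prov, keep, stage) {
    dropped <- cl$checklist_id[!keep]
    obs_keep <- !(obs$checklist_id %in% dropped)
    prov <- add_provenance(prov, stage, sum(!keep), sum(!obs_keep))
    list(cl = cl[keep, ], obs = obs[obs_keep, ], prov = prov)
  }

  s <- drop_stage(cl, obs, prov, cl$complete %in% TRUE, "incomplete")
  in_ext <- s$cl$lon >= grid$origin_lon & s$cl$lon <= grid_max_lon(grid) &
    s$cl$lat >= grid$origin_lat & s$cl$lat <= grid_max_lat(grid)
  s <- drop_stage(s$cl, s$obs, s$prov, in_ext, "out_of_extent")

  grouped <- s$cl[!is.na(s$cl$group_id), ]
  if (nrow(grouped) > 0L) {
    keep_ids <- grouped |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(keep_id = min(.data$checklist_id), .groups = "drop")
    is_dup <- !is.na(s$cl$group_id) &
      !(s$cl$checklist_id %in% keep_ids$keep_id)
  } else {
    is_dup <- rep(FALSE, nrow(s$cl))
  }
  s <- drop_stage(s$cl, s$obs, s$prov, !is_dup, "shared_duplicate")

  checklist_table(s$cl, s$obs, s$prov)
}

#' Read a species status list from CSV
#'
#' Columns: `species` plus logical flags `exotic`, `vagrant`, `extinct`,
#' `marine`.
#'
#' @param path Path to the status CSV.
#' @return A tibble of species status flags.
#' @export
read_status <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species", "exotic", "vagrant", "extinct", "marine")
  if (!all(need %in% names(df))) {
    rlang::abort("Status CSV must have columns species, exotic, vagrant, extinct, marine.",
                 class = "adequacy_schema_error")
  }
  df |> dplyr::mutate(species = as.character(.data$species),
                      dplyr::across(c("exotic", "vagrant", "extinct", "marine"),
                                    as.logical))
}

#' Filter observations: species status and out-of-range (vagrant) records
#'
#' Removes observations of species flagged exotic, vagrant, extinct or
#' marine, then removes observations falling in grid cells outside the
#' species' gridded range (such records are assumed to be vagrants).
#' Checklists are *retained* even when all their observations are removed:
#' they still represent survey effort and contribute to cell richness
#' denominators and to checklist counts in the spatial-bias metric.
#'
#' @param table A [checklist_table()] (normally output of
#'   [filter_checklists()]).
#' @param status Status tibble (see [read_status()]); must cover every
#'   observed species.
#' @param ranges Range table (`species`, `col`, `row`, `cell`).
#' @param grid A [grid_spec()].
#' @return A filtered [checklist_table()] with updated provenance.
#' @export
filter_observations <- function(table, status, ranges, grid) {
  obs <- table$observations
  missing_status <- setdiff(unique(obs$species), status$species)
  if (length(missing_status) > 0L) {
    rlang::abort(sprintf("No status entry for species: %s.",
                         paste(sort(missing_status), collapse = ", ")),
                 class = "adequacy_missing_status_error")
  }
  flagged <- status$species[status$exotic | status$vagrant |
                              status$extinct | status$marine]
  keep1 <- !(obs$species %in% flagged)
  prov <- add_provenance(table$provenance, "status_excluded", 0L, sum(!keep1))
  obs <- obs[keep1, ]

  retained <- setdiff(unique(obs$species), ranges$species)
  if (length(retained) > 0L) {
    rlang::abort(sprintf("Retained species with no range cells: %s.",
                         paste(sort(retained), collapse = ", ")),
                 class = "adequacy_missing_range_error")
  }
  cl_cells <- add_cell(table$checklists, grid) |>
    dplyr::select("checklist_id", "cell")
  in_range <- obs |>
    dplyr::left_join(cl_cells, by = "checklist_id") |>
    dplyr::left_join(dplyr::mutate(ranges[, c("species", "cell")], in_rng = TRUE),
                     by = c("species", "cell")) |>
    dplyr::pull(.data$in_rng)
  keep2 <- in_range %in% TRUE
  prov <- add_provenance(prov, "out_of_range", 0L, sum(!keep2))
  checklist_table(table$checklists, obs[keep2, ], prov)
}

#' Filter a checklist table to one source programme
#'
#' @param table A [checklist_table()].
#' @param source Source tag (e.g. `"ebird"`, `"birdata"`) or `NULL` /
#'   `"combined"` for all data.
#' @return A [checklist_table()] restricted to checklists with that source.
#' @export
filter_source <- function(table, source) {
  if (is.null(source) || identical(source, "combined")) return(table)
  keep <- table$checklists$source %in% source
  cl <- table$checklists[keep, ]
  obs <- table$observations[table$observations$checklist_id %in%
                              cl$checklist_id, ]
  checklist_table(cl, obs, table$provenance)
}

#' Mean count per species
#'
#' Arithmetic mean of the numeric counts of each species' observations.
#' Present-only records (count `NA`) are excluded; species with no numeric
#' counts get `NA`.
#'
#' @param table A [checklist_table()].
#' @param species Optional character vector restricting the output.
#' @return A tibble (`species`, `average_count`).
#' @export
average_count <- function(table, species = NULL) {
  out <- table$observations |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      average_count = if (all(is.na(.data$count))) NA_real_
                      else mean(.data$count, na.rm = TRUE),
      .groups = "drop")
  if (!is.null(species)) {
    out <- tibble::tibble(species = species) |>
      dplyr::left_join(out, by = "species")
  }
  out
}

#' Write the occurrence rows of a checklist table to CSV
#'
#' One observation per row with its checklist's header fields repeated — the
#' dialect [read_occurrences()] reads back. Present-only counts are written
#' as the `"X"` marker. Checklists left without observations are omitted, so
#' write it before observation-level filtering when effort must round-trip.
#'
#' @param table A [checklist_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(table, path) {
  df <- table$observations |>
    dplyr::left_join(table$checklists, by = "checklist_id") |>
    dplyr::mutate(count = ifelse(is.na(.data$count), "X",
                                 format(.data$count, trim = TRUE))) |>
    dplyr::select("checklist_id", "species", "count", "lon", "lat", "year",
                  "complete", "group_id", "source")
  readr::write_csv(df, path, na = "")
  invisible(path)
}
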