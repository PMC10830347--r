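write_occ_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(rows, path, na = "")
  path
}

occ_rows <- function() {
  tibble::tibble(
    checklist_id = c("c1", "c1", "c2"),
    species = c("spA", "spB", "spA"),
    count = c("2", "X", "4"),
    lon = c(0.5, 0.5, 1.5), lat = c(0.5, 0.5, 0.5),
    year = 2001, complete = TRUE,
    group_id = NA_character_, source = "ebird")
}

test_that("occurrence CSVs group rows into checklists and keep present-only markers", {
  tbl <- read_occurrences(write_occ_csv(occ_rows()))
  expect_equal(nrow(tbl$checklists), 2L)
  expect_equal(nrow(tbl$observations), 3L)
  b <- tbl$observations[tbl$observations$species == "spB", ]
  expect_true(is.na(b$count))  # "X" retained as present-only
  expect_equal(tbl$observations$count[tbl$observations$checklist_id == "c2"], 4)
})

test_that("column mapping loads foreign headers and flags missing columns", {
  rows <- occ_rows() |>
    dplyr::rename(SAMPLING.EVENT = checklist_id, SCI.NAME = species,
                  OBS.COUNT = count, LONGITUDE = lon, LATITUDE = lat,
                  YR = year, ALL.OBS = complete, GROUP.ID = group_id,
                  PROJ = source)
  path <- write_occ_csv(rows)
  map <- occurrence_column_map(
    checklist_id = "SAMPLING.EVENT", species = "SCI.NAME",
    count = "OBS.COUNT", lon = "LONGITUDE", lat = "LATITUDE", year = "YR",
    complete = "ALL.OBS", group_id = "GROUP.ID", source = "PROJ")
  tbl <- read_occurrences(path, map)
  expect_equal(nrow(tbl$checklists), 2L)
  expect_error(read_occurrences(path), class = "adequacy_schema_error")
})

test_that("empty files warn and unparseable rows are skipped with a count", {
  empty <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(occ_rows()[0, ], empty)
  expect_warning(tbl <- read_occurrences(empty), "empty")
  expect_equal(nrow(tbl$checklists), 0L)

  rows <- occ_rows()
  rows$lat[2] <- NA
  expect_warning(tbl <- read_occurrences(write_occ_csv(rows)), "1 unparseable")
  expect_equal(nrow(tbl$observations), 2L)
  expect_equal(tbl$provenance$observations_removed[
    tbl$provenance$stage == "unparseable"], 1L)
})

toy_table <- function() {
  # 6 checklists: 1 incomplete, 2 sharing a group, 1 outside the extent
  cl <- dplyr::bind_rows(
    cl_row("c1", 0.5, 0.5),
    cl_row("c2", 1.5, 0.5, complete = FALSE),
    cl_row("c3", 2.5, 0.5, group_id = "g1"),
    cl_row("c4", 2.5, 0.5, group_id = "g1"),
    cl_row("c5", -3.0, 0.5),
    cl_row("c6", 3.5, 3.5))
  obs <- dplyr::bind_rows(
    obs_row("c1", "spA", 2), obs_row("c2", "spA", 1),
    obs_row("c3", "spB", 5), obs_row("c4", "spB", 5),
    obs_row("c5", "spA", 1), obs_row("c6", "spB", NA))
  make_table(cl, obs)
}

test_that("checklist filters drop incomplete, out-of-extent and shared duplicates", {
  g <- grid_spec(0, 0, 1, 5, 5)
  out <- filter_checklists(toy_table(), g)
  expect_setequal(out$checklists$checklist_id, c("c1", "c3", "c6"))
  prov <- out$provenance
  expect_equal(prov$checklists_removed[prov$stage == "incomplete"], 1L)
  expect_equal(prov$checklists_removed[prov$stage == "out_of_extent"], 1L)
  expect_equal(prov$checklists_removed[prov$stage == "shared_duplicate"], 1L)
  # deterministic dedup: lexicographically smallest id survives
  expect_true("c3" %in% out$checklists$checklist_id)
  expect_false("c4" %in% out$checklists$checklist_id)
})

test_that("provenance counts sum to the raw totals", {
  g <- grid_spec(0, 0, 1, 5, 5)
  raw <- toy_table()
  out <- filter_checklists(raw, g)
  expect_equal(nrow(out$checklists) + sum(out$provenance$checklists_removed),
               nrow(raw$checklists))
  expect_equal(nrow(out$observations) + sum(out$provenance$observations_removed),
               nrow(raw$observations))
})

test_that("filtering is idempotent", {
  g <- grid_spec(0, 0, 1, 5, 5)
  once <- filter_checklists(toy_table(), g)
  twice <- filter_checklists(once, g)
  expect_equal(twice$checklists, once$checklists)
  expect_equal(twice$observations, once$observations)
  expect_equal(sum(twice$provenance$checklists_removed),
               sum(once$provenance$checklists_removed))
})

status_for <- function(species, flag = NULL) {
  st <- tibble::tibble(species = species, exotic = FALSE, vagrant = FALSE,
                       extinct = FALSE, marine = FALSE)
  if (!is.null(flag)) st[[flag]][1] <- TRUE
  st
}

test_that("observation filters remove flagged species and out-of-range records", {
  g <- grid_spec(0, 0, 1, 5, 5)
  tbl <- filter_checklists(toy_table(), g)
  ranges <- tibble::tibble(
    species = c("spA", "spB"),
    col = c(0L, 2L), row = c(0L, 0L)) |>
    dplyr::mutate(cell = cell_index(col, row, g))
  # spB at c6 (cell (3,3)) is outside spB's range -> vagrant record removed
  out <- filter_observations(tbl, status_for(c("spA", "spB")), ranges, g)
  expect_setequal(paste(out$observations$checklist_id, out$observations$species),
                  c("c1 spA", "c3 spB"))
  # the emptied checklist c6 is retained as survey effort
  expect_true("c6" %in% out$checklists$checklist_id)

  # exotic species removed wholesale
  out2 <- filter_observations(tbl, status_for(c("spA", "spB"), "exotic"),
                              ranges, g)
  expect_false("spA" %in% out2$observations$species)

  expect_error(filter_observations(tbl, status_for("spA"), ranges, g),
               class = "adequacy_missing_status_error")
  expect_error(filter_observations(tbl, status_for(c("spA", "spB")),
                                   ranges[1, ], g),
               class = "adequacy_missing_range_error")
})

test_that("no surviving observation lies outside its species' range", {
  for (seed in 1:5) {
    w <- random_small_world(seed, vagrant_record_frac = 0.1)
    cl_cells <- add_cell(w$table$checklists, w$cfg$grid)
    joined <- dplyr::left_join(w$table$observations,
                               cl_cells[, c("checklist_id", "cell")],
                               by = "checklist_id")
    in_range <- paste(joined$species, joined$cell) %in%
      paste(w$ranges$species, w$ranges$cell)
    expect_true(all(in_range))
  }
})

test_that("average count uses numeric counts only", {
  cl <- dplyr::bind_rows(cl_row("c1", 0.5, 0.5), cl_row("c2", 1.5, 0.5))
  obs <- dplyr::bind_rows(
    obs_row("c1", "spA", 2), obs_row("c2", "spA", 4),
    obs_row("c2", "spA", NA),                 # present-only excluded
    obs_row("c1", "spB", NA),                 # all present-only -> NA
    obs_row("c1", "spC", 7))
  ac <- average_count(make_table(cl, obs))
  expect_equal(ac$average_count[ac$species == "spA"], 3)
  expect_true(is.na(ac$average_count[ac$species == "spB"]))
  expect_equal(ac$average_count[ac$species == "spC"], 7)
})

test_that("source filtering restricts checklists and their observations", {
  cl <- dplyr::bind_rows(cl_row("c1", 0.5, 0.5, source = "ebird"),
                         cl_row("c2", 1.5, 0.5, source = "birdata"))
  obs <- dplyr::bind_rows(obs_row("c1", "spA"), obs_row("c2", "spA"))
  tbl <- make_table(cl, obs)
  eb <- filter_source(tbl, "ebird")
  expect_equal(eb$checklists$checklist_id, "c1")
  expect_equal(eb$observations$checklist_id, "c1")
  expect_equal(nrow(filter_source(tbl, "combined")$checklists), 2L)
})

test_that("occurrence tables round-trip through the CSV dialect", {
  w <- random_small_world(4)
  raw <- gen_checklists(w$cfg, w$world)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(raw, path)
  back <- read_occurrences(path)
  kept <- raw$checklists[raw$checklists$checklist_id %in%
                           raw$observations$checklist_id, ]
  expect_setequal(back$checklists$checklist_id, kept$checklist_id)
  expect_equal(nrow(back$observations), nrow(raw$observations))
  ro <- dplyr::arrange(raw$observations, checklist_id, species)
  bo <- dplyr::arrange(back$observations, checklist_id, species)
  expect_equal(bo$count, ro$count)
})
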