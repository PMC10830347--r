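# A small hand-built world used for the worked examples:
# grid 3x1; spA range {cell(0,0), cell(1,0)}, spB range {cell(0,0)};
# checklists: 2 in cell(0,0) (both record spA, one records spB),
# 1 in cell(1,0) recording nothing.
hand_world <- function() {
  g <- grid_spec(0, 0, 1, 3, 1)
  ranges <- tibble::tibble(
    species = c("spA", "spA", "spB"),
    col = c(0L, 1L, 0L), row = 0L) |>
    dplyr::mutate(cell = cell_index(col, row, g))
  cl <- dplyr::bind_rows(cl_row("c1", 0.2, 0.5), cl_row("c2", 0.7, 0.5),
                         cl_row("c3", 1.5, 0.5))
  obs <- dplyr::bind_rows(obs_row("c1", "spA"), obs_row("c2", "spA"),
                          obs_row("c1", "spB"))
  list(g = g, ranges = ranges, table = make_table(cl, obs))
}

test_that("cell inventories tally expected, observed and effort per range cell", {
  hw <- hand_world()
  inv <- build_inventories(hw$table, hw$ranges, hw$g)
  expect_equal(nrow(inv$cells), 2L)  # cell (2,0) is in no range -> omitted
  c00 <- inv$cells[inv$cells$col == 0, ]
  expect_equal(c00$n_expected, 2L)
  expect_equal(c00$n_observed, 2L)
  expect_equal(c00$n_checklists, 2L)
  expect_equal(c00$ic, 1)
  c10 <- inv$cells[inv$cells$col == 1, ]
  expect_equal(c10$n_expected, 1L)
  expect_equal(c10$n_observed, 0L)   # surveyed but species missed
  expect_equal(c10$n_checklists, 1L)
  expect_equal(c10$ic, 0)
})

test_that("inventory completeness is observed over expected richness", {
  expect_equal(inventory_completeness(3L, 4L), 0.75)
  expect_equal(inventory_completeness(0L, 5L), 0)
  expect_equal(inventory_completeness(4L, 4L), 1)
  expect_error(inventory_completeness(0L, 0L),
               class = "adequacy_undefined_cell_error")
})

test_that("per-species metrics match their defining formulas on the hand world", {
  hw <- hand_world()
  inv <- build_inventories(hw$table, hw$ranges, hw$g)
  # spA: IC 1.0 and 0.0 over its two cells
  expect_equal(mic("spA", hw$ranges, inv), 0.5)
  expect_equal(trc("spA", hw$ranges, inv), 0.5)  # recorded in 1 of 2 cells
  # effort [2, 1]: H = 0.5 * (|2/3 - 1/2| + |1/3 - 1/2|) = 1/6
  expect_equal(csb("spA", hw$ranges, inv), 1 - 1 / 6)
  # spB: single-cell range, fully detected, effort forced uniform
  expect_equal(mic("spB", hw$ranges, inv), 1)
  expect_equal(trc("spB", hw$ranges, inv), 1)
  expect_equal(csb("spB", hw$ranges, inv), 1)
})

test_that("the total-variation bias statistic matches direct evaluation", {
  # all effort in 1 of 4 cells: H = (0.75 + 3 * 0.25) / 2 = 0.75, CSB = 0.25
  expect_equal(h_total_variation(c(4, 0, 0, 0)), 0.75)
  expect_equal(h_total_variation(rep(5, 4)), 0)
  expect_equal(h_total_variation(10), 0)  # single cell: p = e forced
})

test_that("closed forms: uniform, single-cell and concentrated effort", {
  g <- grid_spec(0, 0, 1, 4, 1)
  ranges <- tibble::tibble(species = "sp", col = 0:3, row = 0L) |>
    dplyr::mutate(cell = cell_index(col, row, g))
  uniform <- make_table(
    purrr::map_dfr(0:3, function(c_) purrr::map_dfr(1:5, function(i)
      cl_row(sprintf("u%d_%d", c_, i), c_ + 0.5, 0.5))),
    purrr::map_dfr(0:3, function(c_) obs_row(sprintf("u%d_1", c_), "sp")))
  a <- compute_adequacy(uniform, ranges, g)
  expect_equal(a$csb, 1)
  expect_equal(a$trc, 1)

  concentrated <- make_table(
    purrr::map_dfr(1:4, function(i) cl_row(paste0("k", i), 0.5, 0.5)),
    obs_row("k1", "sp"))
  b <- compute_adequacy(concentrated, ranges, g)
  expect_equal(b$csb, 0.25)  # = 1/n for an n = 4 cell range

  island <- tibble::tibble(species = "isl", col = 0L, row = 0L) |>
    dplyr::mutate(cell = cell_index(col, row, g))
  c_ <- compute_adequacy(concentrated, island, g)
  expect_equal(c_$csb, 1)

  empty_effort <- make_table(cl_row("z", 0.5, 0.5)[0, ])
  d <- compute_adequacy(empty_effort, ranges, g)
  expect_true(is.na(d$csb))
  expect_equal(d$trc, 0)
  expect_equal(d$mic, 0)
})

test_that("adequacy equals the brute-force oracle on random worlds", {
  for (seed in 1:10) {
    w <- random_small_world(seed)
    got <- compute_adequacy(w$table, w$ranges, w$cfg$grid)
    want <- oracle_adequacy(w$table, w$ranges, w$cfg$grid)
    expect_equal(got$species, want$species)
    expect_equal(got$mic, want$mic, tolerance = 1e-12)
    expect_equal(got$trc, want$trc, tolerance = 1e-12)
    expect_equal(got$csb, want$csb, tolerance = 1e-12)
    expect_equal(got$n_range_cells, want$n_range_cells)
    expect_equal(got$n_checklists_in_range, want$n_checklists_in_range)
  }
})

test_that("metric bounds hold on random worlds", {
  for (seed in 11:25) {
    w <- random_small_world(seed)
    a <- compute_adequacy(w$table, w$ranges, w$cfg$grid)
    expect_true(all(a$mic >= 0 & a$mic <= 1))
    expect_true(all(a$trc >= 0 & a$trc <= 1))
    defined <- !is.na(a$csb)
    # CSB is undefined exactly when a species has zero in-range checklists
    expect_equal(defined, a$n_checklists_in_range > 0)
    expect_true(all(a$csb[defined] > 1 / a$n_range_cells[defined] - 1e-12))
    expect_true(all(a$csb[defined] <= 1 + 1e-12))
    # CSB = 1 iff effort is exactly uniform over the range cells
    inv <- build_inventories(w$table, w$ranges, w$cfg$grid)
    for (sp in a$species[defined & abs(a$csb - 1) < 1e-12]) {
      cells <- w$ranges$cell[w$ranges$species == sp]
      counts <- inv$cells$n_checklists[match(cells, inv$cells$cell)]
      expect_true(length(unique(counts)) == 1L)
    }
  }
})

test_that("adding a record never decreases MIC or TRC", {
  w <- random_small_world(30)
  base <- compute_adequacy(w$table, w$ranges, w$cfg$grid)
  set.seed(31)
  # add one checklist with one record of a random species inside its range
  sp <- sample(unique(w$ranges$species), 1)
  rcell <- w$ranges[w$ranges$species == sp, ][1, ]
  extra_cl <- cl_row("zzz_new", rcell$col + 0.5, rcell$row + 0.5)
  extra_obs <- obs_row("zzz_new", sp)
  grown <- checklist_table(
    dplyr::bind_rows(w$table$checklists, extra_cl),
    dplyr::bind_rows(w$table$observations, extra_obs))
  after <- compute_adequacy(grown, w$ranges, w$cfg$grid)
  expect_true(all(after$mic >= base$mic - 1e-12))
  expect_true(all(after$trc >= base$trc - 1e-12))
})

test_that("the bias statistic is substitutable via the strategy hook", {
  hw <- hand_world()
  # Kolmogorov-style max deviation instead of total variation
  h_max <- function(counts) {
    p <- counts / sum(counts)
    max(abs(p - 1 / length(counts)))
  }
  a <- compute_adequacy(hw$table, hw$ranges, hw$g, h_fun = h_max)
  expect_equal(a$csb[a$species == "spA"], 1 - abs(2 / 3 - 1 / 2))
})
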