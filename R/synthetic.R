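#' Configuration for a synthetic survey world
#'
#' Defines a complete artificial study system — grid, species ranges, status
#' list, human-density surface, traits, and a checklist-generating process —
#' with known ground truth, so every pipeline stage can be exercised without
#' external data. Defaults describe a desk-scale world: a 10 x 10 one-degree
#' grid, 20 species (2 single-cell island endemics) with log-uniform range
#' sizes between 1 and 40 cells, 500 checklists over 2000-2009 whose
#' placement follows human density (`effort_bias_exponent = 1`), species
#' detectability uniform on 0.3-0.9, 10% present-only counts, 5% incomplete
#' checklists and 5% shared duplicates to exercise the filters.
#'
#' @param seed Integer seed; all world and checklist generation is a pure
#'   function of the configuration, this seed included.
#' @param grid A [grid_spec()].
#' @param n_species Number of analysis species (>= 1).
#' @param range_cells Length-2 bounds of the log-uniform range-size
#'   distribution, in cells.
#' @param n_islands How many of the species are single-cell island endemics.
#' @param effort_total Total number of checklists (>= 0).
#' @param effort_bias_exponent gamma >= 0; checklist placement weight is
#'   proportional to `human_density^gamma` (0 = spatially uniform effort).
#' @param detection_prob_scale Global detection multiplier in (0, 1]; the
#'   probability a checklist detects a species present in its cell is
#'   `detection_prob_scale * detectability(species)`.
#' @param detectability_range Bounds of the per-species detectability draw.
#' @param years Integer vector of survey years.
#' @param per_year_effort_weights Optional simplex of length `length(years)`;
#'   `NULL` = uniform.
#' @param present_only_frac Fraction of observation counts replaced by the
#'   present-only marker.
#' @param incomplete_frac Fraction of checklists flagged non-complete.
#' @param shared_frac Fraction of checklists duplicated as shared group
#'   copies.
#' @param vagrant_record_frac Fraction of observations re-labelled to a
#'   species not mapped in that cell (out-of-range records for the vagrant
#'   filter to remove).
#' @param sources,source_probs Source tags and their sampling probabilities.
#' @param n_exotic,n_vagrant,n_extinct,n_marine Extra species generated with
#'   the corresponding status flag set (their records must be filtered out).
#' @return An object of class `world_config`.
#' @export
world_config <- function(seed = 1,
                         grid = grid_spec(0, 0, 1, 10, 10),
                         n_species = 20,
                         range_cells = c(1, 40),
                         n_islands = 2,
                         effort_total = 500,
                         effort_bias_exponent = 1,
                         detection_prob_scale = 1,
                         detectability_range = c(0.3, 0.9),
                         years = 2000:2009,
                         per_year_effort_weights = NULL,
                         present_only_frac = 0.1,
                         incomplete_frac = 0.05,
                         shared_frac = 0.05,
                         vagrant_record_frac = 0,
                         sources = c("ebird", "birdata"),
                         source_probs = c(0.6, 0.4),
                         n_exotic = 0, n_vagrant = 0,
                         n_extinct = 0, n_marine = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) >= .Machine$integer.max - 2e6) {
    rlang::abort("`seed` must be a (not too large) integer.",
                 class = "adequacy_config_error")
  }
  n_cells <- grid$n_cols * grid$n_rows
  if (n_species < 1 || effort_total < 0 || n_islands < 0 ||
      n_islands > n_species) {
    rlang::abort("Invalid species or effort counts.",
                 class = "adequacy_config_error")
  }
  if (length(range_cells) != 2L || any(range_cells < 1) ||
      range_cells[1] > range_cells[2]) {
    rlang::abort("`range_cells` must be increasing bounds >= 1.",
                 class = "adequacy_config_error")
  }
  if (range_cells[2] > n_cells) {
    rlang::abort(sprintf(
      "Requested range size (%d cells) exceeds the grid (%d cells).",
      range_cells[2], n_cells), class = "adequacy_config_error")
  }
  if (detection_prob_scale <= 0 || detection_prob_scale > 1 ||
      effort_bias_exponent < 0) {
    rlang::abort("detection_prob_scale must be in (0,1]; gamma must be >= 0.",
                 class = "adequacy_config_error")
  }
  w <- per_year_effort_weights
  if (!is.null(w)) {
    if (length(w) != length(years) || any(w < 0) || sum(w) <= 0) {
      rlang::abort("per_year_effort_weights must be non-negative, match `years`, and sum > 0.",
                   class = "adequacy_config_error")
    }
    w <- w / sum(w)
  }
  structure(list(
    seed = seed, grid = grid, n_species = as.integer(n_species),
    range_cells = as.numeric(range_cells), n_islands = as.integer(n_islands),
    effort_total = as.integer(effort_total),
    effort_bias_exponent = effort_bias_exponent,
    detection_prob_scale = detection_prob_scale,
    detectability_range = detectability_range,
    years = as.integer(years), per_year_effort_weights = w,
    present_only_frac = present_only_frac,
    incomplete_frac = incomplete_frac, shared_frac = shared_frac,
    vagrant_record_frac = vagrant_record_frac,
    sources = sources, source_probs = source_probs / sum(source_probs),
    n_exotic = as.integer(n_exotic), n_vagrant = as.integer(n_vagrant),
    n_extinct = as.integer(n_extinct), n_marine = as.integer(n_marine)),
    class = "world_config")
}

# connected range blob grown by random accretion over the 4-neighbourhood;
# works on flat 1-based cell ids for speed
grow_blob <- function(target, grid) {
  nc <- grid$n_cols; nr <- grid$n_rows
  neighbours <- function(id) {
    c0 <- (id - 1L) %% nc; r0 <- (id - 1L) %/% nc
    c(if (c0 > 0L) id - 1L, if (c0 < nc - 1L) id + 1L,
      if (r0 > 0L) id - nc, if (r0 < nr - 1L) id + nc)
  }
  occ <- logical(nc * nr)
  start <- sample.int(nc * nr, 1L)
  occ[start] <- TRUE
  blob <- integer(target); blob[1L] <- start; k <- 1L
  frontier <- neighbours(start)
  while (k < target && length(frontier) > 0L) {
    i <- sample.int(length(frontier), 1L)
    id <- frontier[i]
    frontier <- frontier[-i]
    if (occ[id]) next
    occ[id] <- TRUE; k <- k + 1L; blob[k] <- id
    nb <- neighbours(id)
    frontier <- c(frontier, nb[!occ[nb]])
  }
  blob <- sort(blob[seq_len(k)])
  tibble::tibble(col = (blob - 1L) %% nc, row = (blob - 1L) %/% nc,
                 cell = blob)
}

#' Generate a synthetic world
#'
#' Draws species ranges (connected blobs grown by seeded random accretion;
#' islands are single cells), a status list, a smooth-gradient-plus-noise
#' human-density surface, and species traits with recorded ground truth
#' (detectability and expected count per species). Fully reproducible from
#' the configuration.
#'
#' @param cfg A [world_config()].
#' @return An object of class `adequacy_world`: list with `ranges`, `status`,
#'   `human_density` (tibble `cell`, `col`, `row`, `density`), `traits`
#'   (including the ground-truth `detectability` and `expected_count`
#'   columns), and `species` (analysis species codes).
#' @export
gen_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  set.seed(cfg$seed)
  grid <- cfg$grid
  n_flagged <- cfg$n_exotic + cfg$n_vagrant + cfg$n_extinct + cfg$n_marine
  n_total <- cfg$n_species + n_flagged
  species <- sprintf("sp%03d", seq_len(n_total))

  sizes <- round(exp(runif(n_total, log(cfg$range_cells[1]),
                           log(cfg$range_cells[2]))))
  sizes <- pmax(1L, pmin(as.integer(sizes), grid$n_cols * grid$n_rows))
  if (cfg$n_islands > 0L) sizes[seq_len(cfg$n_islands)] <- 1L

  blobs <- lapply(sizes, grow_blob, grid = grid)
  ranges <- dplyr::bind_rows(blobs) |>
    dplyr::mutate(species = rep(species, vapply(blobs, nrow, integer(1))),
                  .before = 1)

  flags <- tibble::tibble(
    species = species,
    exotic = FALSE, vagrant = FALSE, extinct = FALSE, marine = FALSE)
  idx <- cfg$n_species
  for (fl in c("exotic", "vagrant", "extinct", "marine")) {
    k <- cfg[[paste0("n_", fl)]]
    if (k > 0L) {
      flags[[fl]][idx + seq_len(k)] <- TRUE
      idx <- idx + k
    }
  }

  all_cells <- tidyr::expand_grid(row = seq_len(grid$n_rows) - 1L,
                                  col = seq_len(grid$n_cols) - 1L)
  human_density <- all_cells |>
    dplyr::mutate(
      cell = cell_index(.data$col, .data$row, grid),
      density = 20 * exp(1.5 * (.data$col + 0.5) / grid$n_cols +
                           1.0 * (.data$row + 0.5) / grid$n_rows +
                           stats::rnorm(dplyr::n(), 0, 0.3))) |>
    dplyr::select("cell", "col", "row", "density")

  traits <- tibble::tibble(
    species = species,
    threat_status = sample(threat_levels, n_total, replace = TRUE,
                           prob = c(0.60, 0.15, 0.12, 0.08, 0.05)),
    taxonomic_uniqueness = stats::rlnorm(n_total, 0, 0.5),
    body_mass = stats::rlnorm(n_total, log(50), 1),
    species_density = stats::rlnorm(n_total, log(5), 0.8),
    detectability = stats::runif(n_total, cfg$detectability_range[1],
                                 cfg$detectability_range[2]),
    expected_count = stats::rlnorm(n_total, log(3), 0.7))

  structure(list(ranges = ranges, status = flags,
                 human_density = human_density, traits = traits,
                 species = species[seq_len(cfg$n_species)], cfg = cfg),
            class = "adequacy_world")
}

#' @export
print.adequacy_world <- function(x, ...) {
  cat(sprintf("<adequacy_world> %d species, %d range cells, %d x %d grid\n",
              length(unique(x$ranges$species)), nrow(x$ranges),
              x$cfg$grid$n_cols, x$cfg$grid$n_rows))
  invisible(x)
}

# truncated-at-1 Poisson draw
rtpois1 <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  pmax(1L, stats::qpois(u, lambda))
}

#' Generate synthetic checklists for a world
#'
#' Places `effort_total` checklists across the grid with per-cell weight
#' proportional to `human_density^gamma` and uniform position within the
#' cell; assigns years (per-year weights), sources, incomplete flags and
#' shared-group duplicates. Each species mapped in a checklist's cell is
#' detected independently with probability
#' `detection_prob_scale * detectability`; counts are Poisson (truncated at
#' 1) around the species' expected count, with a configurable fraction
#' replaced by present-only markers, and a configurable fraction of
#' observations re-labelled out-of-range (vagrant records).
#'
#' @param cfg A [world_config()].
#' @param world Output of [gen_world()] for the same configuration.
#' @return A raw [checklist_table()] (unfiltered).
#' @export
gen_checklists <- function(cfg, world) {
  set.seed(cfg$seed + 1000003L)
  grid <- cfg$grid
  n <- cfg$effort_total
  hd <- world$human_density
  if (n == 0L) {
    return(checklist_table(
      tibble::tibble(checklist_id = character(), lon = numeric(),
                     lat = numeric(), year = integer(), complete = logical(),
                     group_id = character(), source = character()),
      tibble::tibble(checklist_id = character(), species = character(),
                     count = numeric())))
  }
  w <- hd$density ^ cfg$effort_bias_exponent
  pick <- sample.int(nrow(hd), n, replace = TRUE, prob = w)
  lon <- grid$origin_lon + (hd$col[pick] + stats::runif(n)) * grid$cell_size
  lat <- grid$origin_lat + (hd$row[pick] + stats::runif(n)) * grid$cell_size
  yw <- cfg$per_year_effort_weights %||%
    rep(1 / length(cfg$years), length(cfg$years))
  checklists <- tibble::tibble(
    checklist_id = sprintf("CL%06d", seq_len(n)),
    lon = lon, lat = lat,
    year = cfg$years[sample.int(length(cfg$years), n, replace = TRUE,
                                prob = yw)],
    complete = stats::runif(n) >= cfg$incomplete_frac,
    group_id = NA_character_,
    source = sample(cfg$sources, n, replace = TRUE, prob = cfg$source_probs),
    cell = hd$cell[pick])

  det_p <- cfg$detection_prob_scale *
    setNames(world$traits$detectability, world$traits$species)
  lambda <- setNames(world$traits$expected_count, world$traits$species)

  # every (checklist, species-present-in-cell) pair is an independent
  # Bernoulli detection trial
  cand <- dplyr::inner_join(checklists[, c("checklist_id", "cell")],
                            world$ranges[, c("species", "cell")],
                            by = "cell", relationship = "many-to-many")
  hit <- stats::runif(nrow(cand)) < det_p[cand$species]
  obs <- tibble::tibble(checklist_id = cand$checklist_id[hit],
                        species = cand$species[hit])
  if (nrow(obs) > 0L) {
    obs$count <- as.numeric(rtpois1(nrow(obs), lambda[obs$species]))
    obs$count[stats::runif(nrow(obs)) < cfg$present_only_frac] <- NA_real_
    if (cfg$vagrant_record_frac > 0) {
      sp_by_cell <- split(world$ranges$species, world$ranges$cell)
      cl_cell <- setNames(checklists$cell, checklists$checklist_id)
      relabel <- which(stats::runif(nrow(obs)) < cfg$vagrant_record_frac)
      for (i in relabel) {
        here <- sp_by_cell[[as.character(cl_cell[obs$checklist_id[i]])]]
        elsewhere <- setdiff(world$traits$species, here)
        if (length(elsewhere) > 0L) obs$species[i] <- sample(elsewhere, 1L)
      }
    }
  } else {
    obs <- tibble::tibble(checklist_id = character(), species = character(),
                          count = numeric())
  }

  n_shared <- floor(cfg$shared_frac * n)
  if (n_shared > 0L) {
    orig <- sample.int(n, n_shared)
    checklists$group_id[orig] <- sprintf("G%05d", seq_len(n_shared))
    dup <- checklists[orig, ]
    dup$checklist_id <- paste0(dup$checklist_id, "b")
    dup_obs <- obs[obs$checklist_id %in% checklists$checklist_id[orig], ]
    dup_obs$checklist_id <- paste0(dup_obs$checklist_id, "b")
    checklists <- dplyr::bind_rows(checklists, dup)
    obs <- dplyr::bind_rows(obs, dup_obs)
  }
  checklist_table(dplyr::select(checklists, -"cell"), obs)
}

#' Simulate a world and run it through the filters
#'
#' Convenience wrapper: generates the world and its checklists, then applies
#' [filter_checklists()] and [filter_observations()], yielding an
#' analysis-ready table alongside the raw data and ground truth.
#'
#' @param cfg A [world_config()].
#' @return A list: `world` ([gen_world()] output), `raw` (unfiltered
#'   [checklist_table()]), `table` (filtered).
#' @export
simulate_world <- function(cfg) {
  world <- gen_world(cfg)
  raw <- gen_checklists(cfg, world)
  table <- filter_checklists(raw, cfg$grid)
  table <- filter_observations(table, world$status, world$ranges, cfg$grid)
  list(world = world, raw = raw, table = table)
}

#' Convert gridded ranges to rectangle multipolygons
#'
#' Returns, per species, its range as a multipart polygon whose parts are the
#' cell rectangles — the representation used to re-grid a world at a
#' different grain via [rasterize_range()].
#'
#' @param ranges Range table (`species`, `col`, `row`).
#' @param grid The [grid_spec()] the ranges are gridded on.
#' @return A named list (species -> list of polygon parts).
#' @export
ranges_to_polygons <- function(ranges, grid) {
  cs <- grid$cell_size
  split(ranges, ranges$species) |>
    purrr::map(function(df) {
      purrr::pmap(list(df$col, df$row), function(cc, rr) {
        x0 <- grid$origin_lon + cc * cs
        y0 <- grid$origin_lat + rr * cs
        list(outer = matrix(c(x0, y0, x0 + cs, y0, x0 + cs, y0 + cs,
                              x0, y0 + cs), ncol = 2, byrow = TRUE))
      })
    })
}

#' Write a synthetic world's inputs to disk
#'
#' Emits the same file dialects the ingest functions read — occurrence CSV,
#' status CSV, range cell-list CSV, range GeoJSON, trait CSV and
#' human-density CSV — so a generated world round-trips through the file
#' interface.
#'
#' @param world Output of [gen_world()].
#' @param raw Raw [checklist_table()] from [gen_checklists()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_world <- function(world, raw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    occurrences = file.path(dir, "occurrences.csv"),
    status = file.path(dir, "status.csv"),
    ranges_cells = file.path(dir, "ranges_cells.csv"),
    ranges_geojson = file.path(dir, "ranges.geojson"),
    traits = file.path(dir, "traits.csv"),
    human_density = file.path(dir, "human_density.csv"))
  write_occurrences(raw, paths["occurrences"])
  readr::write_csv(world$status, paths["status"])
  write_range_cells(world$ranges, paths["ranges_cells"])
  write_range_geojson(world$ranges, world$cfg$grid, paths["ranges_geojson"])
  readr::write_csv(
    dplyr::select(world$traits, "species", "threat_status",
                  "taxonomic_uniqueness", "body_mass", "species_density"),
    paths["traits"])
  readr::write_csv(world$human_density, paths["human_density"])
  invisible(paths)
}
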