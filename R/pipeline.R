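#' Run the full adequacy pipeline from a configuration
#'
#' Wires the whole analysis — ingest, filtering, metrics, temporal series and
#' trait models — from a single YAML (or list) configuration, writing all
#' artifacts to the output directory. With a `synthetic:` block the inputs
#' are generated by [gen_world()]/[gen_checklists()] (and written alongside
#' the results); otherwise they are read from the configured paths.
#'
#' Configuration schema (YAML keys):
#' \preformatted{
#' seed: 1
#' output_dir: out
#' grid: {origin_lon: 0, origin_lat: 0, cell_size: 1, n_cols: 10, n_rows: 10}
#' years: {from: 2000, to: 2009}
#' modes: [cumulative, annual]
#' source: combined            # or ebird / birdata
#' synthetic: {n_species: 20, effort_total: 500, ...}   # world_config args
#' paths:                      # used when no synthetic block
#'   occurrences: occ.csv
#'   status: status.csv
#'   ranges_cells: ranges.csv  # or ranges_geojson: ranges.geojson
#'   traits: traits.csv
#'   human_density: hd.csv
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param stage Which stages to run: `"all"` or one of `"simulate"`,
#'   `"metrics"`, `"series"`, `"model"` (later stages imply the earlier
#'   computation they need).
#' @param seed,grain,source,output_dir Optional overrides of the config
#'   values (`grain` replaces the grid cell size, keeping the grid extent).
#' @return Invisibly, a list with the computed tables (`adequacy`, `series`,
#'   `models`, ...) and `artifacts` (named vector of files written).
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "metrics",
                                           "series", "model"),
                         seed = NULL, grain = NULL, source = NULL,
                         output_dir = NULL) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) {
    rlang::abort("`config` must be a YAML file path or a list.",
                 class = "adequacy_config_error")
  }
  cfg$seed <- seed %||% cfg$seed %||% 1L
  cfg$source <- source %||% cfg$source %||% "combined"
  out_dir <- output_dir %||% cfg$output_dir %||%
    rlang::abort("Config must set `output_dir`.", class = "adequacy_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  config_hash <- rlang::hash(cfg)
  logf("run start (config hash %s, stage %s)", config_hash, stage)

  g <- cfg$grid %||% list()
  grid <- grid_spec(g$origin_lon %||% 0, g$origin_lat %||% 0,
                    g$cell_size %||% 1, g$n_cols %||% 10, g$n_rows %||% 10)
  if (!is.null(grain)) {
    grid <- grid_spec(grid$origin_lon, grid$origin_lat, grain,
                      max(1L, round(grid$n_cols * grid$cell_size / grain)),
                      max(1L, round(grid$n_rows * grid$cell_size / grain)))
    logf("grain override: %g deg (%d x %d)", grain, grid$n_cols, grid$n_rows)
  }
  years <- if (!is.null(cfg$years)) {
    as.integer(cfg$years$from):as.integer(cfg$years$to)
  } else 1980:2022

  artifacts <- c()
  synthetic <- !is.null(cfg$synthetic)
  if (synthetic) {
    wc <- do.call(world_config,
                  c(list(seed = cfg$seed, grid = grid,
                         years = cfg$synthetic$years %||% years),
                    cfg$synthetic[setdiff(names(cfg$synthetic),
                                          c("seed", "grid", "years"))]))
    world <- gen_world(wc)
    raw <- gen_checklists(wc, world)
    input_dir <- file.path(out_dir, "inputs")
    artifacts <- c(artifacts, write_world(world, raw, input_dir))
    status <- world$status
    ranges <- world$ranges
    species_traits <- dplyr::select(world$traits, "species", "threat_status",
                                    "taxonomic_uniqueness", "body_mass",
                                    "species_density")
    human_density <- world$human_density
    logf("synthetic world: %d species, %d checklists",
         length(world$species), nrow(raw$checklists))
  } else {
    p <- cfg$paths %||% list()
    need <- c("occurrences", "status", "traits", "human_density")
    missing_paths <- need[vapply(need, function(k) is.null(p[[k]]), logical(1))]
    if (is.null(p$ranges_cells) && is.null(p$ranges_geojson)) {
      missing_paths <- c(missing_paths, "ranges_cells|ranges_geojson")
    }
    missing_files <- unlist(lapply(setdiff(need, missing_paths),
                                   function(k) if (!file.exists(p[[k]])) p[[k]]))
    if (length(missing_paths) > 0L || length(missing_files) > 0L) {
      rlang::abort(paste0(
        "Non-synthetic run needs readable input paths. ",
        if (length(missing_paths)) paste("Missing keys:",
                                         paste(missing_paths, collapse = ", ")),
        if (length(missing_files)) paste(" Missing files:",
                                         paste(missing_files, collapse = ", "))),
        class = "adequacy_config_error")
    }
    raw <- read_occurrences(p$occurrences,
                            do.call(occurrence_column_map,
                                    cfg$column_map %||% list()))
    status <- read_status(p$status)
    ranges <- if (!is.null(p$ranges_cells)) read_range_cells(p$ranges_cells, grid)
              else read_range_geojson(p$ranges_geojson, grid)
    species_traits <- readr::read_csv(p$traits, show_col_types = FALSE)
    human_density <- readr::read_csv(p$human_density, show_col_types = FALSE)
    if (!"cell" %in% names(human_density)) {
      human_density$cell <- cell_index(human_density$col, human_density$row, grid)
    }
    logf("read %d checklists, %d species ranges",
         nrow(raw$checklists), dplyr::n_distinct(ranges$species))
  }
  if (stage == "simulate") {
    logf("run complete (simulate only)")
    return(invisible(list(artifacts = artifacts)))
  }

  table <- filter_source(raw, cfg$source)
  table <- filter_checklists(table, grid)
  table <- filter_observations(table, status, ranges, grid)
  analysis_ranges <- ranges |>
    dplyr::anti_join(
      dplyr::filter(status, .data$exotic | .data$vagrant | .data$extinct |
                      .data$marine),
      by = "species")
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(config_hash = config_hash, source = cfg$source,
         grid = unclass(grid),
         n_checklists = nrow(table$checklists),
         n_observations = nrow(table$observations),
         filters = table$provenance),
    prov_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, provenance = prov_path)

  result <- list(table = table, ranges = analysis_ranges, grid = grid)
  adequacy <- compute_adequacy(table, analysis_ranges, grid)
  adequacy_path <- file.path(out_dir, "adequacy.csv")
  write_adequacy(adequacy, adequacy_path)
  artifacts <- c(artifacts, adequacy = adequacy_path)
  result$adequacy <- adequacy
  logf("adequacy computed for %d species", nrow(adequacy))

  if (stage %in% c("all", "series")) {
    modes <- unlist(cfg$modes %||% list("cumulative", "annual"))
    series <- list()
    for (m in modes) {
      pts <- switch(m,
        cumulative = cumulative_series(table, analysis_ranges, grid, years),
        annual = annual_series(table, analysis_ranges, grid, years),
        rlang::abort(sprintf("Unknown mode '%s'.", m),
                     class = "adequacy_config_error"))
      sm <- summarize_series(pts)
      pp <- file.path(out_dir, sprintf("series_%s.csv", m))
      sp <- file.path(out_dir, sprintf("series_%s_summary.csv", m))
      readr::write_csv(pts, pp); readr::write_csv(sm, sp)
      artifacts <- c(artifacts, setNames(c(pp, sp),
                                         paste0("series_", m, c("", "_summary"))))
      series[[m]] <- list(points = pts, summary = sm)
      logf("series (%s): %d points", m, nrow(pts))
    }
    result$series <- series
  }

  if (stage %in% c("all", "model")) {
    traits <- assemble_traits(species_traits, table,
                              analysis_ranges, human_density)
    models <- run_all_models(traits, adequacy)
    cp <- file.path(out_dir, "model_coefficients.csv")
    ep <- file.path(out_dir, "model_exclusions.csv")
    gp <- file.path(out_dir, "model_stats.json")
    readr::write_csv(tidy(models), cp)
    readr::write_csv(models$exclusions, ep)
    jsonlite::write_json(glance(models), gp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts <- c(artifacts, model_coefficients = cp,
                   model_exclusions = ep, model_stats = gp)
    result$models <- models
    logf("models fitted on %d species (%d excluded)",
         models$fits[[1]]$n_species, nrow(models$exclusions))
  }

  logf("run complete")
  result$artifacts <- artifacts
  invisible(result)
}
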