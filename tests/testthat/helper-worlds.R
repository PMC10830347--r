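# Small fixture builders shared across test files.

# hand-assembled checklist table on a unit grid
make_table <- function(checklists, observations = NULL) {
  if (is.null(observations)) {
    observations <- tibble::tibble(checklist_id = character(),
                                   species = character(), count = numeric())
  }
  checklist_table(checklists, observations)
}

cl_row <- function(id, lon, lat, year = 2000, complete = TRUE,
                   group_id = NA_character_, source = "ebird") {
  tibble::tibble(checklist_id = id, lon = lon, lat = lat, year = year,
                 complete = complete, group_id = group_id, source = source)
}

obs_row <- function(id, species, count = 1) {
  tibble::tibble(checklist_id = id, species = species, count = count)
}

# a random small filtered world: grid <= 10x10, <= 20 species
random_small_world <- function(seed, max_dim = 10, max_species = 20,
                               max_effort = 200, years = 2000:2004, ...) {
  set.seed(seed)
  n_cols <- sample(4:max_dim, 1)
  n_rows <- sample(4:max_dim, 1)
  n_sp <- sample(3:max_species, 1)
  cfg <- world_config(
    seed = seed,
    grid = grid_spec(0, 0, 1, n_cols, n_rows),
    n_species = n_sp,
    n_islands = sample(0:min(2, n_sp), 1),
    range_cells = c(1, max(2, floor(n_cols * n_rows / 2))),
    effort_total = sample(20:max_effort, 1),
    effort_bias_exponent = runif(1, 0, 2),
    detection_prob_scale = runif(1, 0.4, 1),
    years = years,
    ...)
  sim <- simulate_world(cfg)
  list(cfg = cfg, world = sim$world, table = sim$table,
       ranges = sim$world$ranges)
}
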