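# Independent brute-force implementations used as oracles. Deliberately
# naive: explicit loops, no shared code with the package internals.

# grid assignment by direct arithmetic (mirrors the half-open convention)
oracle_cell <- function(lon, lat, grid) {
  col <- min(floor((lon - grid$origin_lon) / grid$cell_size + 1e-9),
             grid$n_cols - 1)
  row <- min(floor((lat - grid$origin_lat) / grid$cell_size + 1e-9),
             grid$n_rows - 1)
  row * grid$n_cols + col + 1
}

# per-species adequacy metrics by nested loops over species x cells x records
oracle_adequacy <- function(table, ranges, grid) {
  cl <- as.data.frame(table$checklists)
  obs <- as.data.frame(table$observations)
  cl_cell <- vapply(seq_len(nrow(cl)),
                    function(i) oracle_cell(cl$lon[i], cl$lat[i], grid),
                    numeric(1))
  names(cl_cell) <- cl$checklist_id
  obs_cell <- unname(cl_cell[obs$checklist_id])

  all_cells <- sort(unique(ranges$cell))
  ic <- setNames(numeric(length(all_cells)), all_cells)
  for (c_ in all_cells) {
    expected <- unique(ranges$species[ranges$cell == c_])
    observed <- unique(obs$species[obs_cell == c_])
    ic[as.character(c_)] <- length(observed) / length(expected)
  }

  species_set <- sort(unique(ranges$species))
  out <- lapply(species_set, function(sp) {
    cells <- ranges$cell[ranges$species == sp]
    mic_v <- mean(ic[as.character(cells)])
    trc_v <- mean(vapply(cells, function(c_)
      any(obs$species == sp & obs_cell == c_), logical(1)))
    counts <- vapply(cells, function(c_) sum(cl_cell == c_), numeric(1))
    csb_v <- if (sum(counts) == 0) NA_real_ else {
      n <- length(counts)
      p <- counts / sum(counts)
      1 - 0.5 * sum(abs(p - 1 / n))
    }
    data.frame(species = sp, mic = mic_v, trc = trc_v, csb = csb_v,
               n_range_cells = length(cells),
               n_checklists_in_range = sum(counts))
  })
  do.call(rbind, out)
}

# closed-form OLS via the normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# order-statistic percentile with linear interpolation (quantile type 7)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
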