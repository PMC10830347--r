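#' Define a regular longitude/latitude grid
#'
#' All adequacy metrics are computed on a regular grid of square cells in
#' plain geographic degrees (no projection; all metrics are cell-count based,
#' so cell *areas* never enter the definitions). Cells are indexed by
#' zero-based `(col, row)` with `col` increasing eastward from `origin_lon`
#' and `row` increasing northward from `origin_lat`. A scalar cell id
#' `cell = row * n_cols + col + 1` is used for joins.
#'
#' @param origin_lon,origin_lat Lower-left corner of the grid, in degrees.
#' @param cell_size Cell edge length in degrees (the *grain*); must be > 0.
#' @param n_cols,n_rows Grid dimensions; must be >= 1.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(origin_lon = 110, origin_lat = -45, cell_size = 1,
#'                n_cols = 45, n_rows = 35)
#' assign_cell(151.2, -33.9, g)
#' @export
grid_spec <- function(origin_lon = 110, origin_lat = -45, cell_size = 1,
                      n_cols = 45, n_rows = 35) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat),
            length(origin_lon) == 1, length(origin_lat) == 1)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    rlang::abort("`cell_size` must be a single positive number of degrees.",
                 class = "adequacy_grid_error")
  }
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || is.na(n_rows) || n_cols < 1L || n_rows < 1L) {
    rlang::abort("`n_cols` and `n_rows` must be integers >= 1.",
                 class = "adequacy_grid_error")
  }
  structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size = as.numeric(cell_size),
         n_cols = n_cols, n_rows = n_rows),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g deg, lon [%g, %g), lat [%g, %g)\n",
    x$n_cols, x$n_rows, x$cell_size,
    x$origin_lon, x$origin_lon + x$n_cols * x$cell_size,
    x$origin_lat, x$origin_lat + x$n_rows * x$cell_size))
  invisible(x)
}

grid_max_lon <- function(grid) grid$origin_lon + grid$n_cols * grid$cell_size
grid_max_lat <- function(grid) grid$origin_lat + grid$n_rows * grid$cell_size

#' Scalar cell id from (col, row)
#'
#' @param col,row Zero-based cell indices.
#' @param grid A [grid_spec()].
#' @return Integer vector of 1-based scalar cell ids.
#' @export
cell_index <- function(col, row, grid) {
  as.integer(row) * grid$n_cols + as.integer(col) + 1L
}

#' Cell centre coordinates
#'
#' @inheritParams cell_index
#' @return A tibble with columns `lon`, `lat`.
#' @export
cell_centre <- function(col, row, grid) {
  tibble::tibble(
    lon = grid$origin_lon + (col + 0.5) * grid$cell_size,
    lat = grid$origin_lat + (row + 0.5) * grid$cell_size)
}

# Small forward tolerance so points sitting numerically *on* an interior
# boundary (e.g. 0.6/0.2 = 2.9999...) fall in the upper (lower-inclusive)
# cell, matching the half-open convention exactly in rational arithmetic.
.cell_floor <- function(u) as.integer(floor(u + 1e-9))

#' Assign points to grid cells
#'
#' Cells are half-open, lower-inclusive intervals
#' `[cell_min, cell_min + cell_size)` on both axes; points exactly on the
#' global maximum boundary fold into the last cell so that assignment is a
#' total function on the grid extent.
#'
#' @param lon,lat Numeric vectors of point coordinates in degrees.
#' @param grid A [grid_spec()].
#' @return A tibble with columns `col`, `row`, `cell` (one row per point).
#' @examples
#' g <- grid_spec(0, 0, 1, 10, 10)
#' assign_cell(c(0.5, 1.0), c(0.5, 0), g)
#' @export
assign_cell <- function(lon, lat, grid) {
  stopifnot(length(lon) == length(lat))
  out_lon <- lon < grid$origin_lon | lon > grid_max_lon(grid) | is.na(lon)
  out_lat <- lat < grid$origin_lat | lat > grid_max_lat(grid) | is.na(lat)
  if (any(out_lon) || any(out_lat)) {
    i <- which(out_lon | out_lat)[1]
    bad <- if (out_lon[i]) sprintf("lon = %s", format(lon[i]))
           else sprintf("lat = %s", format(lat[i]))
    rlang::abort(
      sprintf("Point %d (%s) lies outside the grid extent.", i, bad),
      class = "adequacy_extent_error")
  }
  col <- pmin(.cell_floor((lon - grid$origin_lon) / grid$cell_size),
              grid$n_cols - 1L)
  row <- pmin(.cell_floor((lat - grid$origin_lat) / grid$cell_size),
              grid$n_rows - 1L)
  tibble::tibble(col = col, row = row, cell = cell_index(col, row, grid))
}

#' Add cell columns to a data frame of points
#'
#' Data-frame-first wrapper around [assign_cell()]: appends `col`, `row` and
#' `cell` columns computed from the `lon`/`lat` columns.
#'
#' @param df A data frame with `lon` and `lat` columns.
#' @param grid A [grid_spec()].
#' @return `df` as a tibble with `col`, `row`, `cell` appended.
#' @export
add_cell <- function(df, grid) {
  cells <- assign_cell(df$lon, df$lat, grid)
  dplyr::bind_cols(tibble::as_tibble(df),
                   cells[setdiff(names(cells), names(df))])
}

## ---- polygon geometry kernel -----------------------------------------------
## Ranges arrive as polygons (GeoJSON rings) and must be reduced to the set of
## grid cells they overlap with positive area. Each ring is clipped against a
## cell rectangle with the Sutherland-Hodgman algorithm; the clipped area comes
## from the shoelace formula. Holes subtract their clipped area from the
## enclosing outer ring.

# clip ring (n x 2 matrix) to half-plane; side: 1 = keep >= bound ... encoded
# by (axis, keep_greater, bound)
.clip_half <- function(ring, axis, keep_greater, bound) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  vals <- ring[, axis]
  inside <- if (keep_greater) vals >= bound else vals <= bound
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- ring[i, ]; q <- ring[j, ]
    pin <- inside[i]; qin <- inside[j]
    if (pin) out <- rbind(out, p)
    if (xor(pin, qin)) {
      t <- (bound - p[axis]) / (q[axis] - p[axis])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

.clip_ring_to_rect <- function(ring, xmin, xmax, ymin, ymax) {
  r <- .clip_half(ring, 1L, TRUE, xmin)
  r <- .clip_half(r, 1L, FALSE, xmax)
  r <- .clip_half(r, 2L, TRUE, ymin)
  .clip_half(r, 2L, FALSE, ymax)
}

.shoelace <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.as_ring <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) < 2L) {
    rlang::abort("Polygon rings must be numeric with >= 2 columns (lon, lat).",
                 class = "adequacy_geometry_error")
  }
  m <- m[, 1:2, drop = FALSE]
  # drop closing vertex if the ring repeats its first point
  if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

# Normalise the accepted polygon encodings to a list of parts, each
# list(outer = ring, holes = list of rings).
.as_polygon_parts <- function(polygon) {
  if (is.matrix(polygon) || is.data.frame(polygon)) {
    return(list(list(outer = .as_ring(polygon), holes = list())))
  }
  if (is.list(polygon) && !is.null(polygon$outer)) {
    holes <- lapply(polygon$holes %||% list(), .as_ring)
    return(list(list(outer = .as_ring(polygon$outer), holes = holes)))
  }
  if (is.list(polygon)) {
    return(unlist(lapply(polygon, .as_polygon_parts), recursive = FALSE))
  }
  rlang::abort("Unrecognised polygon representation.",
               class = "adequacy_geometry_error")
}

#' Rasterize a range polygon to a set of grid cells
#'
#' Returns every grid cell whose rectangle intersects the polygon with
#' positive area (a mere boundary touch does not include a cell, avoiding
#' spurious single-point inclusions along shared edges). Accepts a single
#' ring (matrix or data frame of lon/lat vertices), a part
#' (`list(outer =, holes =)`), or a list of parts (multipolygon).
#'
#' @param polygon Polygon or multipolygon in lon/lat degrees (see Details).
#' @param grid A [grid_spec()].
#' @param species Optional species code; if given, included as a column.
#' @return A tibble with columns `col`, `row`, `cell` (and `species` if
#'   supplied), one row per overlapped cell — the species' gridded range.
#' @export
rasterize_range <- function(polygon, grid, species = NULL) {
  parts <- .as_polygon_parts(polygon)
  total_area <- sum(vapply(parts, function(p) .shoelace(p$outer), numeric(1)))
  if (length(parts) == 0L || total_area <= 0) {
    rlang::abort("Polygon is empty or degenerate (zero area).",
                 class = "adequacy_geometry_error")
  }
  cs <- grid$cell_size
  area_tol <- 1e-10 * cs * cs
  acc <- new.env(parent = emptyenv())  # cell -> accumulated signed area
  add_area <- function(key, a) {
    k <- as.character(key)
    acc[[k]] <- (acc[[k]] %||% 0) + a
  }
  for (part in parts) {
    rings <- c(list(part$outer), part$holes)
    signs <- c(1, rep(-1, length(part$holes)))
    for (ri in seq_along(rings)) {
      ring <- rings[[ri]]
      if (nrow(ring) < 3L) next
      # candidate cells: those overlapping the ring's bbox, clamped to grid
      c0 <- max(0L, .cell_floor((min(ring[, 1]) - grid$origin_lon) / cs))
      c1 <- min(grid$n_cols - 1L,
                .cell_floor((max(ring[, 1]) - grid$origin_lon) / cs))
      r0 <- max(0L, .cell_floor((min(ring[, 2]) - grid$origin_lat) / cs))
      r1 <- min(grid$n_rows - 1L,
                .cell_floor((max(ring[, 2]) - grid$origin_lat) / cs))
      if (c1 < c0 || r1 < r0) next
      for (cc in c0:c1) {
        xmin <- grid$origin_lon + cc * cs
        for (rr in r0:r1) {
          ymin <- grid$origin_lat + rr * cs
          a <- .shoelace(.clip_ring_to_rect(ring, xmin, xmin + cs,
                                            ymin, ymin + cs))
          if (a > 0) add_area(cell_index(cc, rr, grid), signs[ri] * a)
        }
      }
    }
  }
  keys <- ls(acc)
  areas <- vapply(keys, function(k) acc[[k]], numeric(1))
  cells <- sort(as.integer(keys[areas > area_tol]))
  out <- tibble::tibble(
    col = (cells - 1L) %% grid$n_cols,
    row = (cells - 1L) %/% grid$n_cols,
    cell = cells)
  if (!is.null(species)) out <- dplyr::mutate(out, species = species, .before = 1)
  out
}

#' Read species ranges from a GeoJSON file
#'
#' Reads a FeatureCollection of (Multi)Polygon features and rasterizes each
#' feature's geometry onto `grid`. The species code is taken from the feature
#' property named by `species_property`.
#'
#' @param path Path to a GeoJSON file.
#' @param grid A [grid_spec()].
#' @param species_property Name of the feature property holding the species
#'   code.
#' @return A range table: tibble with columns `species`, `col`, `row`, `cell`.
#' @export
read_range_geojson <- function(path, grid, species_property = "species") {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list(gj)
  purrr::map_dfr(feats, function(f) {
    sp <- f$properties[[species_property]]
    if (is.null(sp)) {
      rlang::abort(sprintf("Feature lacks the '%s' property.", species_property),
                   class = "adequacy_schema_error")
    }
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      rlang::abort(sprintf("Unsupported geometry type '%s'.", geom$type),
                   class = "adequacy_geometry_error"))
    parts <- lapply(polys, function(rings) {
      rings <- lapply(rings, function(r)
        do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]]))))
      list(outer = rings[[1]], holes = rings[-1])
    })
    rasterize_range(parts, grid, species = sp)
  })
}

#' Read pre-gridded species ranges from a cell-list CSV
#'
#' Alternative to polygon rasterization: a CSV with columns `species`, `col`,
#' `row` giving each species' range cells directly.
#'
#' @param path Path to the CSV.
#' @param grid A [grid_spec()] (used to compute scalar cell ids and validate
#'   extent).
#' @return A range table: tibble with columns `species`, `col`, `row`, `cell`.
#' @export
read_range_cells <- function(path, grid) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species", "col", "row")
  if (!all(need %in% names(df))) {
    rlang::abort("Range cell CSV must have columns species, col, row.",
                 class = "adequacy_schema_error")
  }
  if (any(df$col < 0 | df$col >= grid$n_cols | df$row < 0 | df$row >= grid$n_rows)) {
    rlang::abort("Range cells outside the grid extent.",
                 class = "adequacy_extent_error")
  }
  df |>
    dplyr::mutate(species = as.character(.data$species),
                  col = as.integer(.data$col), row = as.integer(.data$row),
                  cell = cell_index(.data$col, .data$row, grid)) |>
    dplyr::distinct(.data$species, .data$col, .data$row, .data$cell)
}

#' Write species ranges as a cell-list CSV
#'
#' @param ranges A range table (`species`, `col`, `row`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_range_cells <- function(ranges, path) {
  readr::write_csv(dplyr::select(ranges, "species", "col", "row"), path)
  invisible(path)
}

#' Write species ranges as GeoJSON rectangles
#'
#' Each species' gridded range is written as a MultiPolygon whose parts are
#' its cell rectangles, yielding a file that [read_range_geojson()] gridded at
#' the same grain reproduces exactly.
#'
#' @param ranges A range table (`species`, `col`, `row`).
#' @param grid A [grid_spec()].
#' @param path Output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_range_geojson <- function(ranges, grid, path) {
  cs <- grid$cell_size
  feats <- ranges |>
    dplyr::group_by(.data$species) |>
    dplyr::group_map(function(df, key) {
      coords <- purrr::pmap(list(df$col, df$row), function(cc, rr) {
        x0 <- grid$origin_lon + cc * cs; y0 <- grid$origin_lat + rr * cs
        list(list(list(x0, y0), list(x0 + cs, y0), list(x0 + cs, y0 + cs),
                  list(x0, y0 + cs), list(x0, y0)))
      })
      list(type = "Feature",
           properties = list(species = key$species),
           geometry = list(type = "MultiPolygon", coordinates = coords))
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
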