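#' Nested geographic grid specification
#'
#' The workflow operates on three nested geographic grids: coarse tiles
#' (default 0.05 degrees) used for compositing and segmentation, primary
#' cells (default 0.005 degrees) that are the unit of labelling and
#' active-learning site selection, and pixels (default 0.000025 degrees,
#' about 2.8 m at the equator, matching high-resolution CubeSat imagery).
#' Each level nests exactly in the level above.
#'
#' @param origin_lon,origin_lat south-west corner of the domain, degrees.
#' @param tile_size tile edge length, degrees.
#' @param primary_size primary-cell edge length, degrees; must divide
#'   `tile_size` exactly.
#' @param pixel_size pixel edge length, degrees; must divide `primary_size`
#'   exactly.
#' @param extent_tiles optional `c(n_cols, n_rows)` giving the domain extent
#'   in tiles; when supplied, [cell_for_point()] rejects points outside it.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon = 0, origin_lat = 0,
                      tile_size = 0.05, primary_size = 0.005,
                      pixel_size = 0.000025, extent_tiles = NULL) {
  stopifnot(tile_size > 0, primary_size > 0, pixel_size > 0)
  if (!is_multiple(tile_size, primary_size))
    stop("tile_size must be an exact integer multiple of primary_size")
  if (!is_multiple(primary_size, pixel_size))
    stop("primary_size must be an exact integer multiple of pixel_size")
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 tile_size = tile_size, primary_size = primary_size,
                 pixel_size = pixel_size, extent_tiles = extent_tiles),
            class = "grid_spec")
}

is_multiple <- function(big, small, tol = 1e-8) {
  r <- big / small
  abs(r - round(r)) < tol && round(r) >= 1
}

level_size <- function(spec, level) {
  switch(level,
         tile = spec$tile_size,
         primary = spec$primary_size,
         stop("unknown grid level: ", level))
}

#' Reference to one grid cell
#'
#' A cell is identified by `(level, col, row)` with column index increasing
#' eastward and row index increasing northward from the grid origin. Cell
#' bounds are half-open: `[lon0, lon0 + s) x [lat0, lat0 + s)`, so every
#' point belongs to exactly one cell per level.
#'
#' @param level `"tile"` or `"primary"`.
#' @param col,row non-negative integer indices.
#' @param spec a [grid_spec()].
#' @return an object of class `cell_ref` with a `bounds` element
#'   `c(lon0, lat0, lon1, lat1)`.
#' @export
cell_ref <- function(level, col, row, spec) {
  stopifnot(level %in% c("tile", "primary"), col >= 0, row >= 0)
  s <- level_size(spec, level)
  lon0 <- spec$origin_lon + col * s
  lat0 <- spec$origin_lat + row * s
  structure(list(level = level, col = as.integer(col), row = as.integer(row),
                 bounds = c(lon0 = lon0, lat0 = lat0,
                            lon1 = lon0 + s, lat1 = lat0 + s)),
            class = "cell_ref")
}

#' @export
format.cell_ref <- function(x, ...) {
  sprintf("%s_c%d_r%d", x$level, x$col, x$row)
}

#' @export
print.cell_ref <- function(x, ...) {
  cat(format(x), sprintf(" [%g,%g) x [%g,%g)\n",
                         x$bounds["lon0"], x$bounds["lon1"],
                         x$bounds["lat0"], x$bounds["lat1"]))
  invisible(x)
}

#' Cell id string for a cell reference
#' @param cell a [cell_ref()].
#' @return character id, e.g. `"tile_c3_r12"`.
#' @export
cell_id <- function(cell) format(cell)

#' Parse a cell id string back into a cell reference
#' @param id character id as produced by [cell_id()].
#' @param spec a [grid_spec()].
#' @return a [cell_ref()].
#' @export
parse_cell_id <- function(id, spec) {
  m <- regmatches(id, regexec("^(tile|primary)_c([0-9]+)_r([0-9]+)$", id))[[1]]
  if (length(m) != 4L) stop("malformed cell id: ", id)
  cell_ref(m[2], as.integer(m[3]), as.integer(m[4]), spec)
}

#' Locate the grid cell containing a point
#'
#' Half-open bounds make the assignment unambiguous: a point on a shared
#' edge belongs to the cell whose interval starts there.
#'
#' @param lon,lat point coordinates, degrees.
#' @param level `"tile"` or `"primary"`.
#' @param spec a [grid_spec()].
#' @return the containing [cell_ref()].
#' @export
cell_for_point <- function(lon, lat, level, spec) {
  s <- level_size(spec, level)
  col <- floor((lon - spec$origin_lon) / s + 1e-12)
  row <- floor((lat - spec$origin_lat) / s + 1e-12)
  if (col < 0 || row < 0)
    stop("point (", lon, ", ", lat, ") lies outside the grid domain")
  if (!is.null(spec$extent_tiles)) {
    per_tile <- spec$tile_size / s
    if (col >= spec$extent_tiles[1] * per_tile ||
        row >= spec$extent_tiles[2] * per_tile)
      stop("point (", lon, ", ", lat, ") lies outside the grid domain")
  }
  cell_ref(level, col, row, spec)
}

#' Enumerate the primary cells nested in a tile
#'
#' @param tile a tile-level [cell_ref()].
#' @param spec a [grid_spec()].
#' @return list of primary-level [cell_ref()]s in row-major order
#'   (south to north, west to east), `(tile_size/primary_size)^2` of them.
#' @export
primary_cells_of <- function(tile, spec) {
  if (!inherits(tile, "cell_ref") || tile$level != "tile")
    stop("primary_cells_of() requires a tile-level cell_ref")
  k <- as.integer(round(spec$tile_size / spec$primary_size))
  out <- vector("list", k * k)
  idx <- 1L
  for (r in seq_len(k) - 1L) {
    for (c in seq_len(k) - 1L) {
      out[[idx]] <- cell_ref("primary", tile$col * k + c, tile$row * k + r, spec)
      idx <- idx + 1L
    }
  }
  out
}

#' Pixel window dimensions of a cell
#'
#' @param cell a [cell_ref()].
#' @param spec a [grid_spec()].
#' @return `c(n_cols, n_rows)` of the pixel raster aligned to the cell; at the
#'   defaults a primary cell is 200 x 200 = 40,000 pixels.
#' @export
raster_window <- function(cell, spec) {
  s <- level_size(spec, cell$level)
  if (!is_multiple(s, spec$pixel_size))
    stop("pixel_size does not divide the ", cell$level, " cell size exactly")
  n <- as.integer(round(s / spec$pixel_size))
  c(n_cols = n, n_rows = n)
}

#' Partition tiles into named areas of interest
#'
#' Mapping regions (AOIs) group tiles so each region gets its own classifier.
#'
#' @param tiles list of tile-level [cell_ref()]s.
#' @param grouping named character vector or data.frame with columns
#'   `tile_id`, `aoi_id` mapping every tile id to an AOI id.
#' @return named list of AOIs, each a list of [cell_ref()]s; every input tile
#'   appears in exactly one AOI.
#' @export
partition_aois <- function(tiles, grouping) {
  ids <- vapply(tiles, cell_id, character(1))
  if (is.data.frame(grouping)) {
    grouping <- setNames(as.character(grouping$aoi_id),
                         as.character(grouping$tile_id))
  }
  missing <- setdiff(ids, names(grouping))
  if (length(missing))
    stop("grouping does not cover tile(s): ", paste(missing, collapse = ", "))
  aoi_of <- grouping[ids]
  split(tiles, factor(aoi_of, levels = unique(aoi_of)))
}

#' Write / read cell reference lists as CSV
#'
#' Columns: `level, col, row, lon0, lat0`. Round-trips exactly.
#' @param cells list of [cell_ref()]s.
#' @param path file path.
#' @export
write_cells_csv <- function(cells, path) {
  df <- data.frame(
    level = vapply(cells, function(c) c$level, character(1)),
    col = vapply(cells, function(c) c$col, integer(1)),
    row = vapply(cells, function(c) c$row, integer(1)),
    lon0 = vapply(cells, function(c) unname(c$bounds["lon0"]), numeric(1)),
    lat0 = vapply(cells, function(c) unname(c$bounds["lat0"]), numeric(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @param spec a [grid_spec()].
#' @export
read_cells_csv <- function(path, spec) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    cell_ref(df$level[i], df$col[i], df$row[i], spec))
}

#' Composite catalog manifest
#'
#' Enumerates the (tile, season) composite products for a tile set: one
#' composite per tile per season, so two seasons over n tiles yields 2n
#' catalog entries.
#'
#' @param tiles list of tile-level [cell_ref()]s.
#' @param seasons character vector of season labels.
#' @return data.frame with columns `tile_id`, `season`.
#' @export
catalog_manifest <- function(tiles, seasons = c("growing", "dry")) {
  ids <- vapply(tiles, cell_id, character(1))
  out <- expand.grid(tile_id = ids, season = seasons,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[order(out$tile_id, out$season), , drop = FALSE]
}
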