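# Matrix-backed raster helpers. A raster is a plain matrix (or 3-D array,
# [row, col, band]) with row 1 at the NORTHERN edge (image convention),
# tied to a grid cell through `raster_geom()`.

#' Raster geometry of a cell's pixel window
#'
#' @param cell a [cell_ref()].
#' @param spec a [grid_spec()].
#' @return list with `nx`, `ny`, `px` (pixel size, degrees) and the cell
#'   bounds; pixel `[1,1]` is the north-west corner pixel.
#' @export
raster_geom <- function(cell, spec) {
  win <- raster_window(cell, spec)
  list(nx = unname(win["n_cols"]), ny = unname(win["n_rows"]),
       px = spec$pixel_size, bounds = cell$bounds)
}

#' Pixel-center coordinates of a raster geometry
#'
#' @param geom a [raster_geom()].
#' @return list of vectors `lon` (length nx, west to east) and `lat`
#'   (length ny, north to south, matching row order).
#' @export
pixel_centers <- function(geom) {
  lon <- geom$bounds["lon0"] + (seq_len(geom$nx) - 0.5) * geom$px
  lat <- geom$bounds["lat1"] - (seq_len(geom$ny) - 0.5) * geom$px
  list(lon = unname(lon), lat = unname(lat))
}

# Reflect-pad a matrix by k rows/cols on each side (edge pixels mirrored,
# edge row itself not duplicated beyond need: standard "reflect" without
# repeating the border sample would fail for k >= n, so use symmetric
# reflection including the border, which is well defined for k < n).
pad_reflect <- function(m, k) {
  n_r <- nrow(m); n_c <- ncol(m)
  stopifnot(k < n_r, k < n_c)
  ri <- c(rev(seq_len(k)), seq_len(n_r), n_r - seq_len(k) + 1L)
  ci <- c(rev(seq_len(k)), seq_len(n_c), n_c - seq_len(k) + 1L)
  m[ri, ci, drop = FALSE]
}

# k x k box sum via 2-D cumulative sums on a reflect-padded matrix.
box_sum <- function(m, k) {
  stopifnot(k %% 2L == 1L)
  h <- (k - 1L) %/% 2L
  p <- pad_reflect(m, h)
  cs <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  z <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  z[-1L, -1L] <- cs
  n_r <- nrow(m); n_c <- ncol(m)
  i1 <- seq_len(n_r); i2 <- i1 + k - 1L
  j1 <- seq_len(n_c); j2 <- j1 + k - 1L
  z[i2 + 1L, j2 + 1L] - z[i1, j2 + 1L] - z[i2 + 1L, j1] + z[i1, j1]
}

#' Moving-window mean and population standard deviation
#'
#' Reflect padding at the edges; the standard deviation uses the population
#' (divide by n) convention.
#'
#' @param m numeric matrix.
#' @param k odd window edge length.
#' @return matrix of the same shape.
#' @export
window_mean <- function(m, k) box_sum(m, k) / (k * k)

#' @rdname window_mean
#' @export
window_sd <- function(m, k) {
  n <- k * k
  mu <- box_sum(m, k) / n
  v <- box_sum(m * m, k) / n - mu * mu
  sqrt(pmax(v, 0))
}

# 3x3 convolution (kernel applied as correlation) with reflect padding.
conv3 <- function(m, kern) {
  p <- pad_reflect(m, 1L)
  n_r <- nrow(m); n_c <- ncol(m)
  out <- matrix(0, n_r, n_c)
  for (di in -1:1) for (dj in -1:1) {
    w <- kern[di + 2L, dj + 2L]
    if (w != 0)
      out <- out + w * p[seq_len(n_r) + 1L + di, seq_len(n_c) + 1L + dj]
  }
  out
}

#' Sobel gradient magnitude
#'
#' @param m numeric matrix.
#' @return matrix of `sqrt(gx^2 + gy^2)` with reflect padding at the edges.
#' @export
sobel_magnitude <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- conv3(m, kx)
  gy <- conv3(m, ky)
  sqrt(gx^2 + gy^2)
}

# Binary dilation with a Chebyshev-disc structuring element of radius r.
dilate_mask <- function(mask, r) {
  m <- mask * 1
  n_r <- nrow(m); n_c <- ncol(m)
  out <- matrix(0, n_r, n_c)
  for (di in -r:r) for (dj in -r:r) {
    si <- pmin(pmax(seq_len(n_r) + di, 1L), n_r)
    sj <- pmin(pmax(seq_len(n_c) + dj, 1L), n_c)
    out <- pmax(out, m[si, sj])
  }
  out > 0
}

min_max_scale <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' Write / read a multi-band raster as TIFF with a CSV georeferencing sidecar
#'
#' Bands are stored as 32-bit float TIFF samples; the sidecar
#' (`<path>.geo.csv`) records the bounding box, pixel size and band names so
#' a raster round-trips through disk.
#'
#' @param x matrix or `[row, col, band]` array.
#' @param path output path (`.tif`).
#' @param geom a [raster_geom()].
#' @param bands optional character band names.
#' @export
write_raster_tiff <- function(x, path, geom, bands = NULL) {
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- data.frame(
    key = c("lon0", "lat0", "lon1", "lat1", "px", "nx", "ny", "bands"),
    value = c(geom$bounds[c("lon0", "lat0", "lon1", "lat1")], geom$px,
              geom$nx, geom$ny,
              paste(bands %||% paste0("b", seq_len(dim(x)[3])),
                    collapse = "|")))
  write.csv(sidecar, paste0(path, ".geo.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @return `read_raster_tiff()` returns a list `values` (array), `geom`,
#'   `bands`.
#' @export
read_raster_tiff <- function(path) {
  v <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(v)) == 2L) v <- array(v, c(dim(v), 1L))
  sc <- read.csv(paste0(path, ".geo.csv"))
  val <- setNames(as.list(sc$value), sc$key)
  geom <- list(nx = as.integer(val$nx), ny = as.integer(val$ny),
               px = as.numeric(val$px),
               bounds = c(lon0 = as.numeric(val$lon0),
                          lat0 = as.numeric(val$lat0),
                          lon1 = as.numeric(val$lon1),
                          lat1 = as.numeric(val$lat1)))
  list(values = v, geom = geom, bands = strsplit(val$bands, "\\|")[[1]])
}
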