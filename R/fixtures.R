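# Seeded synthetic landscapes, daily scene stacks, and simulated labellers.
#
# The landscape is a jittered-grid tessellation: a corner lattice with random
# row/column spacing is jittered (interior corners only), producing a
# contiguous mosaic of irregular quadrilateral "fields". Each field gets a
# cover type; cropland covers are drawn to hit a target areal fraction.
# Cover spectra are chosen so cropland and herbaceous non-cropland overlap
# within a single season but separate in the growing-vs-dry contrast, which
# is what makes the two-season feature set informative.

COVER_TYPES <- c("cropland", "herbaceous", "woody")

# Seasonal endmember spectra (blue, green, red, nir), surface reflectance.
# Cropland: vegetated in the growing season, bright bare soil after harvest.
# Herbaceous: similar phenology but a weaker seasonal swing. Woody: evergreen.
cover_spectra <- function() {
  list(
    growing = rbind(cropland   = c(0.055, 0.095, 0.075, 0.45),
                    herbaceous = c(0.062, 0.102, 0.090, 0.41),
                    woody      = c(0.040, 0.070, 0.050, 0.50)),
    dry     = rbind(cropland   = c(0.115, 0.155, 0.200, 0.290),
                    herbaceous = c(0.102, 0.140, 0.178, 0.300),
                    woody      = c(0.050, 0.080, 0.070, 0.43)))
}

#' Simulated labeller specification
#'
#' @param skill scalar in `[0, 1]`; convenience dial that sets the three
#'   error processes when they are not given explicitly: boundary jitter
#'   `3 * (1 - skill)` pixels, omission `0.6 * (1 - skill)`, commission
#'   `0.4 * (1 - skill)`.
#' @param jitter_px vertex jitter standard deviation, pixels.
#' @param omission_rate probability a true field is skipped.
#' @param commission_rate expected spurious polygons per true field.
#' @param seed labeller-specific seed.
#' @return object of class `labeller_spec`.
#' @export
labeller_spec <- function(skill = 1, jitter_px = NULL, omission_rate = NULL,
                          commission_rate = NULL, seed = 1L) {
  stopifnot(skill >= 0, skill <= 1)
  jitter_px <- jitter_px %||% (3 * (1 - skill))
  omission_rate <- omission_rate %||% (0.6 * (1 - skill))
  commission_rate <- commission_rate %||% (0.4 * (1 - skill))
  stopifnot(omission_rate >= 0, omission_rate <= 1, commission_rate >= 0)
  structure(list(skill = skill, jitter_px = jitter_px,
                 omission_rate = omission_rate,
                 commission_rate = commission_rate, seed = as.integer(seed)),
            class = "labeller_spec")
}

#' Generate a seeded synthetic field landscape
#'
#' @param seed integer seed; the same `(seed, domain, params)` always yields
#'   the identical landscape.
#' @param domain a tile-level [cell_ref()] or list of them (must form a
#'   rectangle in index space for rendering).
#' @param spec a [grid_spec()].
#' @param params list: `crop_fraction` target areal cropland fraction
#'   (default 0.3), `mean_field_px` approximate mean field edge length in
#'   pixels (default 14), `size_cv` spacing variability (default 0.45),
#'   `corner_jitter` corner jitter as a fraction of mean spacing (default
#'   0.25).
#' @return object of class `synthetic_landscape`: `polygons` (fields with
#'   cover class), `cover` (per-field cover type), `geom` (raster geometry
#'   of the full domain), `truth_mask` (cropland 0/1 raster),
#'   `cover_raster` (integer cover index raster), `field_raster` (field id
#'   raster), `crop_fraction` realized areal fraction.
#' @export
make_landscape <- function(seed, domain, spec, params = list()) {
  p <- modifyList(list(crop_fraction = 0.3, mean_field_px = 14,
                       size_cv = 0.45, corner_jitter = 0.25), params)
  if (p$crop_fraction < 0 || p$crop_fraction > 1)
    stop("infeasible cropland fraction")
  geom <- domain_geom(domain, spec)
  set.seed(derive_seed(seed, "landscape"))
  nx <- geom$nx; ny <- geom$ny
  k <- p$mean_field_px
  n_cx <- max(2L, round(nx / k)); n_cy <- max(2L, round(ny / k))
  xs <- cumsum(rlnorm(n_cx, 0, p$size_cv)); xs <- c(0, xs / max(xs)) * nx
  ys <- cumsum(rlnorm(n_cy, 0, p$size_cv)); ys <- c(0, ys / max(ys)) * ny
  cx <- outer(xs, rep(1, n_cy + 1L))
  cy <- outer(rep(1, n_cx + 1L), ys)
  jit <- p$corner_jitter * k
  ji <- matrix(rnorm(length(cx), 0, jit), nrow(cx))
  jj <- matrix(rnorm(length(cy), 0, jit), nrow(cy))
  ji[c(1, n_cx + 1L), ] <- 0; jj[c(1, n_cx + 1L), ] <- 0
  ji[, c(1, n_cy + 1L)] <- 0; jj[, c(1, n_cy + 1L)] <- 0
  cx <- pmin(pmax(cx + ji, 0), nx)
  cy <- pmin(pmax(cy + jj, 0), ny)

  polys <- list(); cover <- character(0)
  n_fields <- n_cx * n_cy
  is_crop <- rep(FALSE, n_fields)
  if (p$crop_fraction > 0) {
    n_crop <- round(p$crop_fraction * n_fields)
    is_crop[sample.int(n_fields, n_crop)] <- TRUE
  }
  idx <- 0L
  for (i in seq_len(n_cx)) for (j in seq_len(n_cy)) {
    idx <- idx + 1L
    # corner coords in pixel units -> lon/lat (y measured from north edge)
    px <- rbind(c(cx[i, j], cy[i, j]), c(cx[i + 1L, j], cy[i + 1L, j]),
                c(cx[i + 1L, j + 1L], cy[i + 1L, j + 1L]),
                c(cx[i, j + 1L], cy[i, j + 1L]))
    ring <- cbind(geom$bounds["lon0"] + px[, 1] * geom$px,
                  geom$bounds["lat1"] - px[, 2] * geom$px)
    cls <- if (is_crop[idx]) "cropland" else
      sample(c("herbaceous", "woody"), 1L, prob = c(0.6, 0.4))
    polys[[idx]] <- polygon_geom(ring, class = if (is_crop[idx])
      "annual cropland" else cls)
    cover[idx] <- cls
  }

  # rasterize field membership by nearest assignment: every pixel belongs to
  # the field whose (jittered) quadrilateral contains its center; quads
  # tessellate, so containment is exclusive up to edges.
  field_raster <- matrix(0L, ny, nx)
  for (f in seq_along(polys)) {
    mask <- rasterize_polygons(polys[f], geom)
    field_raster[mask == 1L & field_raster == 0L] <- f
  }
  # edge pixels missed by the center rule (on shared edges): assign nearest
  # labelled neighbor
  if (any(field_raster == 0L)) {
    zero <- which(field_raster == 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(zero))) {
      i <- zero[r, 1]; j <- zero[r, 2]
      for (d in 1:3) {
        nb <- field_raster[max(1, i - d):min(ny, i + d),
                           max(1, j - d):min(nx, j + d)]
        nb <- nb[nb > 0]
        if (length(nb)) { field_raster[i, j] <- nb[1]; break }
      }
    }
  }
  cover_idx <- match(cover, COVER_TYPES)
  cover_raster <- matrix(cover_idx[field_raster], ny, nx)
  truth_mask <- (cover_raster == 1L) * 1L
  structure(list(polygons = polys, cover = cover, geom = geom,
                 truth_mask = truth_mask, cover_raster = cover_raster,
                 field_raster = field_raster,
                 crop_fraction = mean(truth_mask),
                 seed = seed, params = p),
            class = "synthetic_landscape")
}

domain_geom <- function(domain, spec) {
  if (inherits(domain, "cell_ref")) return(raster_geom(domain, spec))
  geoms <- lapply(domain, raster_geom, spec = spec)
  b <- sapply(geoms, function(g) g$bounds)
  bounds <- c(lon0 = min(b["lon0", ]), lat0 = min(b["lat0", ]),
              lon1 = max(b["lon1", ]), lat1 = max(b["lat1", ]))
  px <- geoms[[1]]$px
  list(nx = as.integer(round((bounds["lon1"] - bounds["lon0"]) / px)),
       ny = as.integer(round((bounds["lat1"] - bounds["lat0"]) / px)),
       px = px, bounds = bounds)
}

#' True crop polygons of a landscape
#' @param landscape a [make_landscape()] result.
#' @return list of `fm_polygon`s with class `"annual cropland"`.
#' @export
landscape_crop_polygons <- function(landscape) {
  landscape$polygons[landscape$cover == "cropland"]
}

#' Render a dated scene stack over a landscape
#'
#' Per date, reflectance is the cover's spectrum (linearly interpolated
#' between the growing- and dry-season endmembers by day of year) scaled by
#' a per-field brightness factor, plus Gaussian noise. Injected cloud blobs
#' raise all bands (the blue band most); shadow blobs depress the NIR band.
#' The clean truth (noise- and atmosphere-free seasonal composite) is
#' returned for oracle tests.
#'
#' @param landscape a [make_landscape()] result.
#' @param dates vector of `Date`s (at least one).
#' @param atmosphere list: `cloud_prob` per-date probability a cloud field is
#'   injected (default 0.3), `shadow_prob` (default 0.2), `noise_sd`
#'   reflectance noise (default 0.015), `blob_px` blob radius in pixels
#'   (default a third of the raster), `field_brightness_sd` lognormal sd of
#'   the per-field brightness factor (default 0.08), `seed`.
#' @return list: `stack` (scene stack consumable by [composite_tile()]:
#'   `values [row, col, band, date]`, `dates`, `valid`, `geom`),
#'   `truth` (list of `growing` and `dry` clean `[row, col, band]` arrays),
#'   `cloud` / `shadow` (`[row, col, date]` logical arrays of injected
#'   contamination).
#' @export
render_time_series <- function(landscape, dates, atmosphere = list()) {
  if (!length(dates)) stop("empty date list")
  a <- modifyList(list(cloud_prob = 0.3, shadow_prob = 0.2, noise_sd = 0.025,
                       blob_px = NULL, field_brightness_sd = 0.16,
                       seed = landscape$seed), atmosphere)
  dates <- as.Date(dates)
  geom <- landscape$geom
  nx <- geom$nx; ny <- geom$ny; nd <- length(dates)
  sp <- cover_spectra()
  set.seed(derive_seed(a$seed, "render"))
  n_fields <- length(landscape$polygons)
  bright <- rlnorm(n_fields, 0, a$field_brightness_sd)
  bright_px <- matrix(bright[landscape$field_raster], ny, nx)
  cover_px <- landscape$cover_raster

  season_frac <- function(d) {
    # 1 = peak growing (mid-July), 0 = peak dry (mid-January)
    doy <- as.integer(format(d, "%j"))
    0.5 + 0.5 * cos(2 * pi * (doy - 196) / 365)
  }
  clean_at <- function(frac) {
    arr <- array(0, c(ny, nx, 4))
    for (cv in seq_along(COVER_TYPES)) {
      sel <- cover_px == cv
      if (!any(sel)) next
      spec_mix <- frac * sp$growing[cv, ] + (1 - frac) * sp$dry[cv, ]
      for (b in 1:4)
        arr[, , b][sel] <- spec_mix[b] * bright_px[sel]
    }
    arr
  }
  truth <- list(growing = clean_at(1), dry = clean_at(0))

  vals <- array(0, c(ny, nx, 4, nd))
  cloud <- array(FALSE, c(ny, nx, nd))
  shadow <- array(FALSE, c(ny, nx, nd))
  blob_px <- a$blob_px %||% max(4L, round(min(nx, ny) / 3))
  blob <- function() {
    cx <- runif(1, 1, nx); cy <- runif(1, 1, ny)
    r <- runif(1, blob_px / 2, blob_px)
    dx <- outer(rep(1, ny), seq_len(nx)) - cx
    dy <- outer(seq_len(ny), rep(1, nx)) - cy
    dx^2 + dy^2 <= r^2
  }
  for (t in seq_len(nd)) {
    frac <- season_frac(dates[t])
    sc <- clean_at(frac)
    if (a$noise_sd > 0)
      sc <- sc + array(rnorm(length(sc), 0, a$noise_sd), dim(sc))
    if (runif(1) < a$cloud_prob) {
      cl <- blob()
      cloud[, , t] <- cl
      add <- c(0.45, 0.38, 0.35, 0.30)  # clouds are bright, most in blue
      for (b in 1:4) sc[, , b][cl] <- sc[, , b][cl] + add[b]
    }
    if (runif(1) < a$shadow_prob) {
      sh <- blob()
      shadow[, , t] <- sh
      sc[, , 4][sh] <- sc[, , 4][sh] * 0.25  # shadow knocks down NIR
      for (b in 1:3) sc[, , b][sh] <- sc[, , b][sh] * 0.7
    }
    vals[, , , t] <- pmin(pmax(sc, 0), 1)
  }
  list(stack = list(values = vals, dates = dates,
                    valid = array(TRUE, c(ny, nx, nd)), geom = geom),
       truth = truth, cloud = cloud, shadow = shadow)
}

#' Simulate one labeller's annotation of a cell
#'
#' Truth polygons intersecting the cell are vertex-jittered, randomly
#' omitted, and spurious polygons are added, per the labeller's error
#' model. Deterministic for a given `(spec$seed, cell)`.
#'
#' @param truth_polys list of true field `fm_polygon`s (e.g.
#'   [landscape_crop_polygons()]).
#' @param lspec a [labeller_spec()].
#' @param cell a primary-level [cell_ref()].
#' @param spec a [grid_spec()].
#' @return object of class `annotation`: `polygons`, `labeller_id`,
#'   `cell_id`.
#' @export
simulate_labeller <- function(truth_polys, lspec, cell, spec) {
  geom <- raster_geom(cell, spec)
  set.seed(derive_seed(lspec$seed, paste0("label-", cell_id(cell))))
  b <- cell$bounds
  jd <- lspec$jitter_px * spec$pixel_size
  out <- list()
  n_kept <- 0L
  for (poly in truth_polys) {
    ring <- poly$rings[[1]]
    # only label fields that intersect the cell (bbox test is enough for the
    # tessellated truth)
    if (max(ring[, 1]) < b["lon0"] || min(ring[, 1]) >= b["lon1"] ||
        max(ring[, 2]) < b["lat0"] || min(ring[, 2]) >= b["lat1"]) next
    if (runif(1) < lspec$omission_rate) next
    jring <- ring + matrix(rnorm(length(ring), 0, jd), nrow(ring))
    out[[length(out) + 1L]] <- polygon_geom(jring, class = poly$class)
    n_kept <- n_kept + 1L
  }
  n_spur <- if (lspec$commission_rate > 0)
    stats::rpois(1, lspec$commission_rate * max(1L, n_kept)) else 0L
  for (s in seq_len(n_spur)) {
    w <- runif(1, 2, 6) * spec$pixel_size * 4
    cx <- runif(1, b["lon0"], b["lon1"]); cy <- runif(1, b["lat0"], b["lat1"])
    ang <- runif(1, 0, pi / 2)
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    sq <- rbind(c(-w, -w), c(w, -w), c(w, w), c(-w, w)) %*% rot
    out[[length(out) + 1L]] <-
      polygon_geom(sweep(sq, 2, c(cx, cy), "+"), class = "annual cropland")
  }
  structure(list(polygons = out,
                 labeller_id = paste0("labeller_seed", lspec$seed),
                 cell_id = cell_id(cell)),
            class = "annotation")
}
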