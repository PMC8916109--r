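# Polygon utilities. A ring is an open n x 2 matrix of (lon, lat) vertices
# (first vertex not repeated). A polygon is list(rings = list(outer, holes...),
# class = <character>); the outer ring is rings[[1]].

#' Construct a polygon
#' @param outer n x 2 (lon, lat) matrix, open ring.
#' @param holes optional list of hole rings.
#' @param class thematic class label.
#' @return object of class `fm_polygon`.
#' @export
polygon_geom <- function(outer, holes = list(), class = "annual cropland") {
  outer <- as.matrix(outer)
  if (nrow(outer) >= 2 && all(outer[1, ] == outer[nrow(outer), ]))
    outer <- outer[-nrow(outer), , drop = FALSE]
  if (nrow(outer) < 3) stop("polygon ring needs at least 3 vertices")
  structure(list(rings = c(list(outer), holes), class = class),
            class = "fm_polygon")
}

ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Planar ring area (square degrees) and centroid
#' @param ring open n x 2 ring matrix.
#' @return `ring_area()`: absolute shoelace area; `ring_centroid()`:
#'   area-weighted centroid `c(lon, lat)`.
#' @export
ring_area <- function(ring) abs(ring_area_signed(ring))

#' @rdname ring_area
#' @export
ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-15) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

#' Geodesic polygon area in hectares
#'
#' Outer-ring geodesic area (WGS84, via `geosphere`) minus hole areas.
#' @param poly an `fm_polygon`.
#' @return area in hectares.
#' @export
polygon_area_ha <- function(poly) {
  a <- abs(geosphere::areaPolygon(close_ring(poly$rings[[1]])))
  if (length(poly$rings) > 1)
    for (h in poly$rings[-1]) a <- a - abs(geosphere::areaPolygon(close_ring(h)))
  a / 1e4
}

close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

#' Points-in-polygon test (even-odd rule over all rings)
#'
#' @param pts m x 2 matrix of points.
#' @param poly an `fm_polygon`.
#' @return logical vector: inside the outer ring and not inside any hole.
#' @export
points_in_polygon <- function(pts, poly) {
  inside <- mgcv::in.out(close_ring(poly$rings[[1]]), pts)
  if (length(poly$rings) > 1)
    for (h in poly$rings[-1]) inside <- inside & !mgcv::in.out(close_ring(h), pts)
  inside
}

#' Rasterize polygons onto a raster geometry (pixel-center rule)
#'
#' A pixel is 1 iff its center lies inside any of the polygons.
#'
#' @param polys list of `fm_polygon`s.
#' @param geom a [raster_geom()].
#' @return ny x nx 0/1 integer matrix.
#' @export
rasterize_polygons <- function(polys, geom) {
  out <- matrix(0L, geom$ny, geom$nx)
  if (!length(polys)) return(out)
  ctr <- pixel_centers(geom)
  for (poly in polys) {
    bb <- apply(poly$rings[[1]], 2, range)
    jj <- which(ctr$lon >= bb[1, 1] & ctr$lon <= bb[2, 1])
    ii <- which(ctr$lat >= bb[1, 2] & ctr$lat <= bb[2, 2])
    if (!length(ii) || !length(jj)) next
    pts <- cbind(rep(ctr$lon[jj], each = length(ii)),
                 rep(ctr$lat[ii], times = length(jj)))
    inside <- points_in_polygon(pts, poly)
    sub <- matrix(inside, length(ii), length(jj))
    out[ii, jj] <- pmax(out[ii, jj], sub * 1L)
  }
  out
}

# --- label raster -> rings (pixel-edge tracing) ------------------------------

# Trace the boundary rings of a binary mask. Returns rings in pixel-corner
# coordinates: corner (x, y) with x in 0..nx (column edges, west->east) and
# y in 0..ny (row edges, north->south; row r spans y in [r-1, r]).
# Directed edges are emitted clockwise around each region pixel; at
# corner-touching pixels the most-clockwise continuation is taken so
# diagonally touching regions stay separate rings.
trace_mask_rings <- function(mask) {
  n_r <- nrow(mask); n_c <- ncol(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  m <- matrix(FALSE, n_r + 2L, n_c + 2L)
  m[cbind(idx[, 1] + 1L, idx[, 2] + 1L)] <- TRUE
  edges <- list(); k <- 0L
  r <- idx[, 1] + 1L; c <- idx[, 2] + 1L
  # edge encoded as from-corner (x0,y0) -> to-corner (x1,y1), corners in
  # padded-corner coords; convert at the end by subtracting 1.
  add <- function(x0, y0, x1, y1) {
    k <<- k + 1L
    edges[[k]] <<- cbind(x0, y0, x1, y1)
  }
  up    <- !m[cbind(r - 1L, c)]
  down  <- !m[cbind(r + 1L, c)]
  left  <- !m[cbind(r, c - 1L)]
  right <- !m[cbind(r, c + 1L)]
  # pixel (r,c) occupies x in [c-1,c], y in [r-1,r] (unpadded coords; padded
  # here, fix later). Clockwise in image coords (y down): top edge east,
  # right edge south, bottom edge west, left edge north.
  if (any(up))    add(c[up] - 1L,    r[up] - 1L,    c[up],          r[up] - 1L)
  if (any(right)) add(c[right],      r[right] - 1L, c[right],       r[right])
  if (any(down))  add(c[down],       r[down],       c[down] - 1L,   r[down])
  if (any(left))  add(c[left] - 1L,  r[left],       c[left] - 1L,   r[left] - 1L)
  e <- do.call(rbind, edges)
  # map corners to integer keys
  key <- function(x, y) x * (n_r + 3L) + y
  from <- key(e[, 1], e[, 2])
  # successor lookup: edges grouped by from-corner
  ord <- order(from)
  e <- e[ord, , drop = FALSE]
  from <- from[ord]
  starts <- c(1L, which(diff(from) != 0) + 1L)
  grp_of <- findInterval(seq_len(nrow(e)), starts)
  first_of_key <- setNames(starts, from[starts])
  used <- rep(FALSE, nrow(e))
  dirs <- cbind(e[, 3] - e[, 1], e[, 4] - e[, 2])
  rings <- list()
  for (start in seq_len(nrow(e))) {
    if (used[start]) next
    ring <- list()
    cur <- start
    repeat {
      used[cur] <- TRUE
      ring[[length(ring) + 1L]] <- e[cur, 1:2]
      nxt_key <- as.character(key(e[cur, 3], e[cur, 4]))
      i0 <- unname(first_of_key[nxt_key])
      if (is.na(i0)) break
      # candidates sharing the from-corner
      cand <- i0
      while (cand[length(cand)] < nrow(e) &&
             from[cand[length(cand)] + 1L] == from[i0])
        cand <- c(cand, cand[length(cand)] + 1L)
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # prefer the most-clockwise turn relative to the current direction
        # (image coords, y down: cross d x e > 0 is the clockwise turn that
        # keeps following the same region around a corner-touch)
        d <- dirs[cur, ]
        turn <- d[1] * dirs[cand, 2] - d[2] * dirs[cand, 1]
        cand <- cand[order(-turn)]
      }
      cur <- cand[1]
    }
    rings[[length(rings) + 1L]] <-
      do.call(rbind, ring) - 1L  # back to unpadded corner coords
  }
  rings
}

# Convert a pixel-corner ring to lon/lat using a raster geometry.
corner_ring_to_lonlat <- function(ring, geom) {
  cbind(geom$bounds["lon0"] + ring[, 1] * geom$px,
        geom$bounds["lat1"] - ring[, 2] * geom$px)
}

#' Vectorize the regions of a label raster
#'
#' Traces exact pixel-edge boundaries for each requested label. The largest
#' ring (by absolute area) is the outer ring; remaining rings are holes.
#'
#' @param labels integer label matrix (row 1 = north).
#' @param geom a [raster_geom()].
#' @param keep labels to vectorize (default: all positive labels).
#' @return named list (by label) of `fm_polygon`s in lon/lat.
#' @export
vectorize_regions <- function(labels, geom, keep = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (!is.null(keep)) ids <- intersect(ids, keep)
  out <- list()
  for (id in ids) {
    rings <- trace_mask_rings(labels == id)
    if (!length(rings)) next
    ll <- lapply(rings, corner_ring_to_lonlat, geom = geom)
    areas <- vapply(ll, ring_area, numeric(1))
    o <- which.max(areas)
    out[[as.character(id)]] <-
      polygon_geom(ll[[o]], holes = ll[-o], class = "annual cropland")
  }
  out
}

# --- simplification ----------------------------------------------------------

# Effective (triangle) area of each interior vertex of a closed ring.
vis_effective_areas <- function(ring) {
  n <- nrow(ring)
  prev <- ring[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- ring[c(seq_len(n)[-1], 1), , drop = FALSE]
  abs((prev[, 1] - ring[, 1]) * (nxt[, 2] - ring[, 2]) -
      (nxt[, 1] - ring[, 1]) * (prev[, 2] - ring[, 2])) / 2
}

#' Visvalingam line simplification of a ring
#'
#' Iteratively removes the vertex with the smallest effective (triangle)
#' area while that area is below `tolerance`.
#'
#' @param ring open n x 2 ring matrix.
#' @param tolerance effective-area threshold, in the ring's coordinate units
#'   squared.
#' @return simplified open ring matrix (possibly fewer than 3 vertices, in
#'   which case the caller should drop the polygon).
#' @export
visvalingam <- function(ring, tolerance) {
  while (nrow(ring) > 3) {
    ea <- vis_effective_areas(ring)
    i <- which.min(ea)
    if (ea[i] >= tolerance) break
    ring <- ring[-i, , drop = FALSE]
  }
  if (nrow(ring) == 3) {
    ea <- vis_effective_areas(ring)
    if (min(ea) < tolerance) ring <- ring[-which.min(ea), , drop = FALSE]
  }
  ring
}

# --- GeoJSON I/O -------------------------------------------------------------

#' Write polygons as a GeoJSON FeatureCollection
#'
#' @param polys list of `fm_polygon`s.
#' @param path output path.
#' @param properties optional data.frame of per-feature properties.
#' @export
write_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    poly <- polys[[i]]
    coords <- lapply(poly$rings, function(r) {
      rc <- close_ring(r)
      lapply(seq_len(nrow(rc)), function(j) c(rc[j, 1], rc[j, 2]))
    })
    props <- list(class = poly$class)
    if (!is.null(properties))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#' @param path GeoJSON file path.
#' @return list with `polygons` (list of `fm_polygon`) and `properties`
#'   (data.frame or NULL).
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  stopifnot(identical(g$type, "FeatureCollection"))
  polys <- list(); props <- list()
  for (f in g$features) {
    rings <- lapply(f$geometry$coordinates, function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]]))))
    cls <- f$properties$class %||% "annual cropland"
    polys[[length(polys) + 1L]] <-
      polygon_geom(rings[[1]], holes = rings[-1], class = cls)
    props[[length(props) + 1L]] <- f$properties
  }
  list(polygons = polys,
       properties = if (length(props))
         do.call(rbind, lapply(props, function(p)
           as.data.frame(p, stringsAsFactors = FALSE))) else NULL)
}
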