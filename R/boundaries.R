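# Field delineation: edge synthesis from the dry-season composite and the
# probability map, marker-seeded compact watershed, region-adjacency-graph
# merging, probability filtering, polygon refinement, and cross-tile seam
# merging.

#' Combined edge image for segmentation
#'
#' The dry-season composite is mean-shift filtered (joint spatial/range
#' window), then Sobel gradient magnitudes are computed for the green, red
#' and NIR bands (each min-max scaled to `[0, 1]` per tile) and for the
#' cropland probability map, and the four edge images are summed. Equal
#' per-source scaling keeps any one source from dominating the sum.
#'
#' @param dry `seasonal_composite` (or `[row, col, 4]` array).
#' @param prob probability matrix co-registered with the composite.
#' @param spatial_radius mean-shift spatial window radius, pixels.
#' @param range_radius mean-shift range (reflectance) radius on the scaled
#'   bands.
#' @param max_iter mean-shift iteration cap.
#' @return non-negative edge-strength matrix.
#' @export
compute_edge_image <- function(dry, prob, spatial_radius = 3L,
                               range_radius = 0.1, max_iter = 10L) {
  v <- if (inherits(dry, "seasonal_composite")) dry$values else dry
  if (!identical(dim(v)[1:2], dim(prob)))
    stop("composite and probability map shapes differ")
  bands <- v[, , 2:4, drop = FALSE]  # green, red, nir
  scaled <- bands
  for (b in 1:3) scaled[, , b] <- min_max_scale(bands[, , b])
  ms <- meanshift_filter(scaled, spatial_radius, range_radius, max_iter)
  edge <- matrix(0, dim(v)[1], dim(v)[2])
  for (b in 1:3) edge <- edge + sobel_magnitude(min_max_scale(ms[, , b]))
  edge + sobel_magnitude(prob)
}

#' Mean-shift filter a multi-band image
#'
#' @param img `[row, col, band]` array.
#' @param spatial_radius window radius in pixels.
#' @param range_radius radius in band space (Euclidean).
#' @param max_iter iteration cap.
#' @return filtered array of the same shape.
#' @export
meanshift_filter <- function(img, spatial_radius = 3L, range_radius = 0.1,
                             max_iter = 10L) {
  d <- dim(img)
  out <- .meanshift_filter_cpp(as.numeric(img), d[1], d[2], d[3],
                               as.integer(spatial_radius), range_radius,
                               as.integer(max_iter))
  array(out, d)
}

#' Initial over-segmentation by compact watershed
#'
#' Markers on a regular grid (as close to sqrt(n) x sqrt(n) as the
#' requested count factors) seed a compact watershed of the edge image, so
#' exactly `n_segments` non-empty regions partition the raster; the high
#' default count keeps mean segment size below the expected field size.
#'
#' @param edges edge-strength matrix.
#' @param n_segments number of regions.
#' @param compactness weight of squared seed distance in the flooding cost.
#' @return integer label matrix with labels `1..n_segments`.
#' @export
initial_watershed <- function(edges, n_segments = 6400L, compactness = 0.01) {
  if (any(!is.finite(edges))) stop("edge image must be finite")
  n_r <- nrow(edges); n_c <- ncol(edges)
  if (n_segments > n_r * n_c) stop("more segments than pixels requested")
  g <- marker_grid_dims(n_segments)
  rows <- round((seq_len(g[1]) - 0.5) / g[1] * n_r + 0.5)
  cols <- round((seq_len(g[2]) - 0.5) / g[2] * n_c + 0.5)
  seeds <- cbind(rep(rows, times = g[2]), rep(cols, each = g[1]))
  .compact_watershed_cpp(edges, seeds, compactness)
}

marker_grid_dims <- function(n) {
  r <- floor(sqrt(n))
  while (r >= 1 && n %% r != 0) r <- r - 1
  c(r, n %/% r)
}

#' Merge adjacent regions through a region-adjacency graph
#'
#' Nodes carry the pixel-count and per-band mean of the normalized
#' (`[0, 1]`-scaled per tile) colors; edge weights are the Euclidean
#' distance between adjacent nodes' means. The globally most-similar pair
#' is merged repeatedly while the minimum weight is below `threshold`
#' (merged means are pixel-count weighted; ties break on the smallest
#' (min label, max label) pair).
#'
#' @param segments integer label matrix.
#' @param bands `[row, col, k]` array of image bands (normalized per tile
#'   before distance computation).
#' @param threshold merge threshold on the color distance.
#' @return relabelled integer matrix (labels compacted to `1..n_regions`).
#' @export
merge_regions <- function(segments, bands, threshold = 0.05) {
  d <- dim(bands)
  nb <- d[3]
  norm <- bands
  for (b in seq_len(nb)) norm[, , b] <- min_max_scale(bands[, , b])
  labs <- as.vector(segments)
  n0 <- max(labs)
  counts <- tabulate(labs, n0)
  means <- matrix(0, n0, nb)
  for (b in seq_len(nb)) {
    s <- rowsum(as.vector(norm[, , b]), labs)
    means[as.integer(rownames(s)), b] <- s / counts[as.integer(rownames(s))]
  }
  # adjacency from horizontal + vertical neighbour pairs
  a <- segments[, -ncol(segments)]; b_ <- segments[, -1]
  v1 <- cbind(as.vector(a), as.vector(b_))
  a <- segments[-nrow(segments), ]; b_ <- segments[-1, ]
  v2 <- cbind(as.vector(a), as.vector(b_))
  pr <- rbind(v1, v2)
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  pr <- unique(cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2])))

  parent <- seq_len(n0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edge_w <- function(i, j) sqrt(sum((means[i, ] - means[j, ])^2))
  w <- vapply(seq_len(nrow(pr)), function(k) edge_w(pr[k, 1], pr[k, 2]),
              numeric(1))
  repeat {
    if (!nrow(pr)) break
    o <- order(w, pr[, 1], pr[, 2])
    k <- o[1]
    if (w[k] >= threshold) break
    i <- pr[k, 1]; j <- pr[k, 2]
    # merge j into i (pixel-count weighted mean)
    tot <- counts[i] + counts[j]
    means[i, ] <- (counts[i] * means[i, ] + counts[j] * means[j, ]) / tot
    counts[i] <- tot
    parent[j] <- i
    # rewire edges of j to i, drop the merged edge, dedupe, recompute weights
    pr[pr == j] <- i
    keep <- pr[, 1] != pr[, 2]
    pr <- cbind(pmin(pr[keep, 1], pr[keep, 2]), pmax(pr[keep, 1], pr[keep, 2]))
    pr <- unique(pr, MARGIN = 1)
    w <- vapply(seq_len(nrow(pr)), function(k2) edge_w(pr[k2, 1], pr[k2, 2]),
                numeric(1))
  }
  root <- vapply(seq_len(n0), find, integer(1))
  newlab <- match(root, sort(unique(root)))
  matrix(newlab[labs], nrow(segments), ncol(segments))
}

#' Retain segments whose mean cropland probability exceeds 0.5
#'
#' Vectorizes the label raster and keeps the polygons of regions whose mean
#' predicted probability is strictly greater than 0.5.
#'
#' @param segments integer label matrix.
#' @param prob probability matrix.
#' @param geom the tile [raster_geom()].
#' @param tile_id optional tile id recorded on each field.
#' @return a `field_set`: list with `polygons`, and a data.frame `fields`
#'   of `field_id`, `area_ha`, `mean_prob`, `tile_id`.
#' @export
filter_by_probability <- function(segments, prob, geom, tile_id = NA) {
  ids <- sort(unique(as.vector(segments)))
  ids <- ids[ids > 0]
  mean_p <- vapply(ids, function(id)
    mean(prob[segments == id], na.rm = TRUE), numeric(1))
  keep <- ids[!is.na(mean_p) & mean_p > 0.5]
  polys <- vectorize_regions(segments, geom, keep = keep)
  fields <- data.frame(
    field_id = paste0(ifelse(is.na(tile_id), "field", tile_id), "_",
                      names(polys)),
    area_ha = vapply(polys, polygon_area_ha, numeric(1)),
    mean_prob = mean_p[match(as.integer(names(polys)), ids)],
    tile_id = tile_id, row.names = NULL)
  structure(list(polygons = unname(polys), fields = fields),
            class = "field_set")
}

#' Refine field polygons
#'
#' Removes interior rings (holes) and smooths boundaries with Visvalingam
#' simplification; polygons collapsing below 3 vertices are dropped.
#'
#' @param fields a `field_set`.
#' @param tolerance effective-area tolerance in pixel areas (default half a
#'   pixel).
#' @param pixel_size pixel edge length in the polygons' coordinate units,
#'   used to convert `tolerance` to coordinate units.
#' @return refined `field_set` (areas recomputed; `mean_prob` kept).
#' @export
refine_polygons <- function(fields, tolerance = 0.5, pixel_size) {
  tol <- tolerance * pixel_size^2
  keep <- logical(length(fields$polygons))
  polys <- list()
  for (i in seq_along(fields$polygons)) {
    ring <- visvalingam(fields$polygons[[i]]$rings[[1]], tol)
    if (nrow(ring) < 3) next
    keep[i] <- TRUE
    polys[[length(polys) + 1L]] <-
      polygon_geom(ring, class = fields$polygons[[i]]$class)
  }
  f <- fields$fields[keep, , drop = FALSE]
  f$area_ha <- vapply(polys, polygon_area_ha, numeric(1))
  structure(list(polygons = polys, fields = f), class = "field_set")
}

#' Merge field polygons across tile seams
#'
#' Fields from adjacent tiles are rasterized onto the shared pixel grid;
#' connected components (8-connectivity is not needed: seam-adjacent pixels
#' are 4-connected on the shared grid) that contain polygons from more than
#' one tile are unioned and re-traced, all other fields pass through
#' unchanged. Idempotent.
#'
#' @param field_sets list of per-tile `field_set`s.
#' @param geom [raster_geom()] of the combined domain.
#' @return a single merged `field_set`.
#' @export
merge_tile_seams <- function(field_sets, geom) {
  all_polys <- list(); src_tile <- character(0); meta <- list()
  for (fs in field_sets) {
    for (i in seq_along(fs$polygons)) {
      all_polys[[length(all_polys) + 1L]] <- fs$polygons[[i]]
      src_tile <- c(src_tile, as.character(fs$fields$tile_id[i]))
      meta[[length(meta) + 1L]] <- fs$fields[i, , drop = FALSE]
    }
  }
  if (!length(all_polys))
    return(structure(list(polygons = list(),
                          fields = data.frame(field_id = character(0),
                                              area_ha = numeric(0),
                                              mean_prob = numeric(0),
                                              tile_id = character(0))),
                     class = "field_set"))
  # label raster of all polygons
  lab <- matrix(0L, geom$ny, geom$nx)
  for (i in seq_along(all_polys)) {
    m <- rasterize_polygons(all_polys[i], geom)
    lab[m == 1L & lab == 0L] <- i
  }
  comp <- connected_components(lab > 0)
  out_polys <- list(); rows <- list()
  done <- rep(FALSE, length(all_polys))
  for (cid in seq_len(max(comp, 0))) {
    members <- unique(lab[comp == cid])
    members <- members[members > 0]
    if (!length(members)) next
    tiles <- unique(src_tile[members])
    if (length(members) == 1L || length(tiles) == 1L) next  # handled below
    mask <- comp == cid
    rings <- trace_mask_rings(mask)
    ll <- lapply(rings, corner_ring_to_lonlat, geom = geom)
    areas <- vapply(ll, ring_area, numeric(1))
    o <- which.max(areas)
    poly <- polygon_geom(ll[[o]], holes = ll[-o])
    out_polys[[length(out_polys) + 1L]] <- poly
    mp <- vapply(members, function(m) meta[[m]]$mean_prob, numeric(1))
    wts <- vapply(members, function(m) meta[[m]]$area_ha, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      field_id = paste(vapply(members, function(m) meta[[m]]$field_id,
                              character(1)), collapse = "+"),
      area_ha = polygon_area_ha(poly),
      mean_prob = sum(mp * wts) / sum(wts),
      tile_id = paste(sort(tiles), collapse = "+"))
    done[members] <- TRUE
  }
  for (i in seq_along(all_polys)) {
    if (done[i]) next
    out_polys[[length(out_polys) + 1L]] <- all_polys[[i]]
    rows[[length(rows) + 1L]] <- meta[[i]]
  }
  structure(list(polygons = out_polys,
                 fields = do.call(rbind, c(rows,
                                           list(make.row.names = FALSE)))),
            class = "field_set")
}

connected_components <- function(mask) {
  n_r <- nrow(mask); n_c <- ncol(mask)
  comp <- matrix(0L, n_r, n_c)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[s] != 0L) next
      comp[s] <- cur
      r <- (s - 1L) %% n_r + 1L; c <- (s - 1L) %/% n_r + 1L
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, s - 1L)
      if (r < n_r) nb <- c(nb, s + 1L)
      if (c > 1L) nb <- c(nb, s - n_r)
      if (c < n_c) nb <- c(nb, s + n_r)
      nb <- nb[mask[nb] & comp[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Per-cell field summaries
#'
#' Assigns each field to the cell containing its centroid and reports the
#' per-cell mean area and field count; empty cells report count 0 and `NA`
#' mean.
#'
#' @param fields a `field_set`.
#' @param cells list of [cell_ref()]s (typically tiles).
#' @param spec a [grid_spec()].
#' @return data.frame `cell_id`, `n_fields`, `mean_size_ha`.
#' @export
summarize_fields <- function(fields, cells, spec) {
  ids <- vapply(cells, cell_id, character(1))
  level <- cells[[1]]$level
  assigned <- rep(NA_character_, length(fields$polygons))
  for (i in seq_along(fields$polygons)) {
    ctr <- ring_centroid(fields$polygons[[i]]$rings[[1]])
    cand <- tryCatch(cell_id(cell_for_point(ctr[1], ctr[2], level, spec)),
                     error = function(e) NA_character_)
    assigned[i] <- cand
  }
  out <- data.frame(cell_id = ids, n_fields = 0L, mean_size_ha = NA_real_)
  for (k in seq_along(ids)) {
    sel <- which(assigned == ids[k])
    out$n_fields[k] <- length(sel)
    if (length(sel))
      out$mean_size_ha[k] <- mean(fields$fields$area_ha[sel])
  }
  out
}
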