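# Edge synthesis, compact watershed, region merging, probability
# filtering, polygon refinement, seam merging and per-cell summaries.

test_that("Sobel magnitude matches a brute-force convolution oracle", {
  set.seed(51)
  m <- matrix(runif(24 * 24), 24)
  got <- sobel_magnitude(m)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  pad <- rbind(m[1, ], m, m[24, ]); pad <- cbind(pad[, 1], pad, pad[, 24])
  for (pt in list(c(1, 1), c(5, 20), c(12, 12), c(24, 3))) {
    i <- pt[1] + 1; j <- pt[2] + 1
    w <- pad[(i - 1):(i + 1), (j - 1):(j + 1)]
    gx <- sum(w * kx); gy <- sum(w * ky)
    expect_equal(got[pt[1], pt[2]], sqrt(gx^2 + gy^2), tolerance = 1e-6)
  }
})

test_that("edge image is zero on constants and peaks at a step", {
  flat <- array(0.4, c(20, 20, 4))
  pflat <- matrix(0.7, 20, 20)
  e <- compute_edge_image(flat, pflat)
  expect_true(all(abs(e) < 1e-12))

  # vertical step in a single band: maximal response at the step columns,
  # zero far away
  stepped <- array(0.2, c(20, 20, 4))
  stepped[, 11:20, 3] <- 0.8
  e2 <- compute_edge_image(stepped, pflat, spatial_radius = 0L)
  expect_true(all(e2[, c(1:8, 13:20)] < 1e-9))
  expect_true(all(e2[, 10:11] > 1))

  expect_error(compute_edge_image(flat, matrix(0.5, 3, 3)), "shapes")
})

test_that("edge synthesis equals the direct Sobel-sum oracle", {
  set.seed(52)
  comp <- array(runif(24 * 24 * 4), c(24, 24, 4))
  prob <- matrix(runif(24 * 24), 24)
  # spatial radius 0 makes the mean-shift step the identity
  got <- compute_edge_image(comp, prob, spatial_radius = 0L)
  oracle <- sobel_magnitude(prob)
  for (b in 2:4) {
    sc <- comp[, , b]
    sc <- (sc - min(sc)) / diff(range(sc))
    oracle <- oracle + sobel_magnitude(sc)
  }
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("mean-shift filtering flattens noise within homogeneous regions", {
  set.seed(53)
  img <- array(0, c(30, 30, 3))
  img[, 1:15, ] <- 0.2; img[, 16:30, ] <- 0.8
  noisy <- img + array(rnorm(length(img), 0, 0.02), dim(img))
  ms <- meanshift_filter(noisy, spatial_radius = 3L, range_radius = 0.1)
  # variance within each half drops, the step is preserved
  expect_lt(sd(ms[, 3:13, 1]), sd(noisy[, 3:13, 1]))
  expect_gt(mean(ms[, 16:30, 1]) - mean(ms[, 1:15, 1]), 0.5)
})

test_that("compact watershed yields the requested partition", {
  set.seed(54)
  e <- matrix(runif(120 * 120), 120)
  w <- initial_watershed(e, n_segments = 100L)
  expect_equal(sort(unique(as.vector(w))), 1:100)
  expect_equal(length(w), 120 * 120)  # labels partition the raster
  expect_error(initial_watershed(matrix(0, 3, 3), n_segments = 100L),
               "segments")
  expect_error(initial_watershed(matrix(c(1, NA, 1, 1), 2), 2L), "finite")
})

test_that("a default tile oversegments into 6,400 sub-half-hectare regions", {
  set.seed(55)
  e <- matrix(runif(2000 * 2000, 0, 0.1), 2000)
  w <- initial_watershed(e, n_segments = 6400L)
  expect_equal(length(unique(as.vector(w))), 6400L)
  # mean segment area under 0.5 ha for a 0.05-degree tile near the equator
  tile <- cell_ref("tile", 0, 0, prod_spec)
  geom <- raster_geom(tile, prod_spec)
  area_ha <- fieldmapr:::domain_area_km2(geom) * 100
  expect_lt(area_ha / 6400, 0.5)
})

test_that("region merging honors the distance threshold", {
  # two flat regions with a controlled color distance, plus an anchor
  # region spanning [0, 1] so per-tile min-max scaling leaves the
  # controlled difference intact
  seg <- matrix(0L, 12, 10)
  seg[1:5, ] <- 1L; seg[6:10, ] <- 2L; seg[11:12, ] <- 3L
  mk_bands <- function(delta) {
    b <- array(0, c(12, 10, 2))
    for (k in 1:2) {
      b[, , k][seg == 1] <- 0.3
      b[, , k][seg == 2] <- 0.3 + delta
      b[11, , k] <- 0; b[12, , k] <- 1
    }
    b
  }
  # per-band difference delta in both bands: distance = delta * sqrt(2)
  merged_close <- merge_regions(seg, mk_bands(0.04 / sqrt(2)),
                                threshold = 0.05)
  merged_far <- merge_regions(seg, mk_bands(0.06 / sqrt(2)),
                              threshold = 0.05)
  expect_equal(length(unique(as.vector(merged_close))), 2L)
  expect_equal(length(unique(as.vector(merged_far))), 3L)

  # threshold 0 is the identity; a huge threshold collapses everything;
  # region count is non-increasing in the threshold
  set.seed(56)
  e <- matrix(runif(60 * 60), 60)
  w <- initial_watershed(e, n_segments = 36L)
  bands <- array(runif(60 * 60 * 3), c(60, 60, 3))
  expect_equal(merge_regions(w, bands, threshold = 0), w)
  expect_equal(length(unique(as.vector(
    merge_regions(w, bands, threshold = 10)))), 1L)
  counts <- vapply(c(0, 0.05, 0.15, 0.5), function(th)
    length(unique(as.vector(merge_regions(w, bands, threshold = th)))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("probability filtering keeps only mean p strictly above 0.5", {
  seg <- matrix(rep(1:3, each = 30), 9, 10)
  geom <- list(nx = 10, ny = 9, px = 0.001,
               bounds = c(lon0 = 0, lat0 = 0, lon1 = 0.01, lat1 = 0.009))
  prob <- matrix(0, 9, 10)
  prob[seg == 1] <- 0.6; prob[seg == 2] <- 0.5; prob[seg == 3] <- 0.49
  fs <- filter_by_probability(seg, prob, geom, tile_id = "t")
  expect_equal(nrow(fs$fields), 1L)
  expect_equal(fs$fields$mean_prob, 0.6)
  expect_true(all(fs$fields$mean_prob > 0.5))
})

test_that("refinement removes holes and collinear vertices", {
  # donut: hole removed, area becomes the outer-ring area
  outer_ring <- rbind(c(0, 0), c(0.01, 0), c(0.01, 0.01), c(0, 0.01))
  hole <- rbind(c(0.004, 0.004), c(0.006, 0.004), c(0.006, 0.006),
                c(0.004, 0.006))
  donut <- polygon_geom(outer_ring, holes = list(hole))
  fs <- structure(list(polygons = list(donut),
                       fields = data.frame(field_id = "f1", area_ha = NA,
                                           mean_prob = 0.9, tile_id = "t")),
                  class = "field_set")
  ref <- refine_polygons(fs, tolerance = 0.5, pixel_size = 1e-4)
  expect_length(ref$polygons[[1]]$rings, 1L)
  expect_equal(ring_area(ref$polygons[[1]]$rings[[1]]), 1e-4)

  # square below tolerance: unchanged
  expect_equal(nrow(ref$polygons[[1]]$rings[[1]]), 4L)

  # collinear vertex (zero effective area) is removed
  tri_plus <- polygon_geom(rbind(c(0, 0), c(0.005, 0), c(0.01, 0),
                                 c(0.01, 0.01), c(0, 0.01)))
  fs2 <- structure(list(polygons = list(tri_plus),
                        fields = data.frame(field_id = "f2", area_ha = NA,
                                            mean_prob = 0.8, tile_id = "t")),
                   class = "field_set")
  ref2 <- refine_polygons(fs2, tolerance = 0.5, pixel_size = 1e-4)
  expect_equal(nrow(ref2$polygons[[1]]$rings[[1]]), 4L)
})

test_that("seam merging unions split fields and is idempotent", {
  spec <- demo_spec
  tA <- cell_ref("tile", 0, 0, spec); tB <- cell_ref("tile", 1, 0, spec)
  gA <- raster_geom(tA, spec); gB <- raster_geom(tB, spec)
  geom <- fieldmapr:::domain_geom(list(tA, tB), spec)
  seam <- tA$bounds["lon1"]

  # one field straddling the seam, one interior to each tile
  straddle_A <- sq_poly(seam - 0.004, 0.01, 0.004)
  straddle_B <- polygon_geom(rbind(c(seam, 0.01), c(seam + 0.004, 0.01),
                                   c(seam + 0.004, 0.014), c(seam, 0.014)))
  lone_A <- sq_poly(0.005, 0.03, 0.006)
  mk_fs <- function(polys, ids, tile)
    structure(list(polygons = polys,
                   fields = data.frame(
                     field_id = ids,
                     area_ha = vapply(polys, polygon_area_ha, numeric(1)),
                     mean_prob = 0.8, tile_id = cell_id(tile))),
              class = "field_set")
  fsA <- mk_fs(list(straddle_A, lone_A), c("a1", "a2"), tA)
  fsB <- mk_fs(list(straddle_B), "b1", tB)

  merged <- merge_tile_seams(list(fsA, fsB), geom)
  expect_equal(nrow(merged$fields), 2L)
  joined <- merged$fields[grepl("\\+", merged$fields$field_id), ]
  expect_equal(nrow(joined), 1L)
  expect_equal(joined$area_ha,
               polygon_area_ha(straddle_A) + polygon_area_ha(straddle_B),
               tolerance = 0.02)
  # untouched fields pass through unchanged
  expect_true("a2" %in% merged$fields$field_id)

  merged2 <- merge_tile_seams(list(merged), geom)
  expect_equal(nrow(merged2$fields), nrow(merged$fields))
  expect_equal(sort(merged2$fields$area_ha), sort(merged$fields$area_ha),
               tolerance = 1e-9)
})

test_that("per-cell summaries conserve counts and report empties", {
  spec <- demo_spec
  cells <- list(cell_ref("tile", 0, 0, spec), cell_ref("tile", 1, 0, spec))
  p1 <- sq_poly(0.01, 0.01, 0.01)   # in tile 0
  p2 <- sq_poly(0.03, 0.02, 0.005)  # in tile 0
  fs <- structure(list(polygons = list(p1, p2),
                       fields = data.frame(
                         field_id = c("f1", "f2"),
                         area_ha = c(1, 3), mean_prob = 0.9,
                         tile_id = "tile_c0_r0")),
                  class = "field_set")
  s <- summarize_fields(fs, cells, spec)
  expect_equal(s$n_fields, c(2L, 0L))
  expect_equal(s$mean_size_ha[1], 2)
  expect_true(is.na(s$mean_size_ha[2]))
  expect_equal(sum(s$n_fields), 2L)
})

test_that("segmenting whole vs split domains conserves field area", {
  # same landscape filtered by a high-confidence probability field, once on
  # the full domain and once per half with seam merging
  l <- make_landscape(17, cell_ref("tile", 0, 0, demo_spec), demo_spec)
  geom <- l$geom
  prob <- ifelse(l$truth_mask == 1, 0.9, 0.1)
  full <- filter_by_probability(l$field_raster * l$truth_mask, prob, geom,
                                tile_id = "full")
  half_cols <- geom$nx / 2
  gL <- list(nx = half_cols, ny = geom$ny, px = geom$px,
             bounds = c(lon0 = unname(geom$bounds["lon0"]),
                        lat0 = unname(geom$bounds["lat0"]),
                        lon1 = unname(geom$bounds["lon0"]) +
                          half_cols * geom$px,
                        lat1 = unname(geom$bounds["lat1"])))
  gR <- list(nx = half_cols, ny = geom$ny, px = geom$px,
             bounds = c(lon0 = unname(gL$bounds["lon1"]),
                        lat0 = unname(geom$bounds["lat0"]),
                        lon1 = unname(geom$bounds["lon1"]),
                        lat1 = unname(geom$bounds["lat1"])))
  segs <- l$field_raster * l$truth_mask
  left <- filter_by_probability(segs[, 1:half_cols],
                                prob[, 1:half_cols], gL, tile_id = "L")
  right <- filter_by_probability(segs[, (half_cols + 1):geom$nx],
                                 prob[, (half_cols + 1):geom$nx], gR,
                                 tile_id = "R")
  merged <- merge_tile_seams(list(left, right), geom)
  expect_equal(sum(merged$fields$area_ha), sum(full$fields$area_ha),
               tolerance = 0.02)
})
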