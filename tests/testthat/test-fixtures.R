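# The synthetic-data generator must be deterministic per seed, hit its
# target cropland fraction on average, and produce contamination that the
# compositing weights can suppress.

small_tile <- cell_ref("tile", 0, 0, demo_spec)

test_that("landscapes are deterministic per seed and differ across seeds", {
  l1 <- make_landscape(5, small_tile, demo_spec)
  l2 <- make_landscape(5, small_tile, demo_spec)
  l3 <- make_landscape(6, small_tile, demo_spec)
  expect_identical(l1$field_raster, l2$field_raster)
  expect_identical(l1$cover, l2$cover)
  expect_false(identical(l1$field_raster, l3$field_raster))
  # every pixel belongs to a field, covers are consistent
  expect_true(all(l1$field_raster > 0))
  expect_equal(sort(unique(as.vector(l1$cover_raster))),
               sort(unique(match(l1$cover, c("cropland", "herbaceous",
                                             "woody")))))
})

test_that("realized cropland fraction tracks the target on average", {
  fr <- vapply(1:50, function(s)
    make_landscape(s, small_tile, demo_spec,
                   params = list(crop_fraction = 0.3))$crop_fraction,
    numeric(1))
  expect_lt(abs(mean(fr) - 0.3), 0.05)

  none <- make_landscape(1, small_tile, demo_spec,
                         params = list(crop_fraction = 0))
  expect_equal(sum(none$truth_mask), 0)
  expect_error(make_landscape(1, small_tile, demo_spec,
                              params = list(crop_fraction = 1.2)),
               "infeasible")
})

test_that("a clean atmosphere renders the truth exactly at season peaks", {
  l <- make_landscape(3, small_tile, demo_spec)
  rt <- render_time_series(l, as.Date("2018-07-15"),
                           atmosphere = list(cloud_prob = 0, shadow_prob = 0,
                                             noise_sd = 0,
                                             field_brightness_sd = 0.16))
  # 2018-07-15 is day 196, the peak of the growing-season interpolation
  expect_equal(rt$stack$values[, , , 1], rt$truth$growing, tolerance = 1e-12)
  expect_error(render_time_series(l, as.Date(character(0))), "empty")
})

test_that("injected clouds raise the blue band above the clean values", {
  l <- make_landscape(4, small_tile, demo_spec)
  rt <- render_time_series(l, demo_dates(),
                           atmosphere = list(cloud_prob = 1, shadow_prob = 0,
                                             noise_sd = 0, seed = 9))
  t_cloudy <- which(apply(rt$cloud, 3, any))[1]
  cl <- rt$cloud[, , t_cloudy]
  clean <- rt$stack$values[, , 1, t_cloudy] * NA
  # recompute the clean scene: same date, atmosphere off
  rt0 <- render_time_series(l, demo_dates()[t_cloudy],
                            atmosphere = list(cloud_prob = 0,
                                              shadow_prob = 0, noise_sd = 0,
                                              seed = 9))
  blue_clean <- rt0$stack$values[, , 1, 1]
  blue_cloud <- rt$stack$values[, , 1, t_cloudy]
  expect_true(all(blue_cloud[cl] > blue_clean[cl]))
})

test_that("weighted compositing of a cloudy stack beats a single date", {
  l <- make_landscape(7, small_tile, demo_spec)
  dates <- demo_dates()
  rt <- render_time_series(l, dates,
                           atmosphere = list(cloud_prob = 0.3,
                                             shadow_prob = 0.2,
                                             noise_sd = 0.01, seed = 2))
  sw <- demo_seasons()$growing
  comp <- composite_tile(rt$stack, sw)
  in_win <- dates >= sw$start & dates <= sw$end
  truth <- rt$truth$growing
  mae <- function(a) mean(abs(a - truth), na.rm = TRUE)
  mae_comp <- mae(comp$values)
  mae_dates <- vapply(which(in_win), function(t)
    mae(rt$stack$values[, , , t]), numeric(1))
  expect_lt(mae_comp, mean(mae_dates))
})

test_that("simulated labellers reproduce truth at full skill and degrade with error", {
  l <- make_landscape(8, small_tile, demo_spec)
  truth <- landscape_crop_polygons(l)
  cells <- primary_cells_of(small_tile, demo_spec)
  cell <- cells[[45]]

  perfect <- simulate_labeller(truth, labeller_spec(skill = 1, seed = 1),
                               cell, demo_spec)
  ref <- annotation(perfect$polygons, "ref", cell)
  sc <- score_assignment(perfect, ref, cell, demo_spec)
  expect_equal(sc$score, 1)

  omit_all <- simulate_labeller(truth,
                                labeller_spec(omission_rate = 1, seed = 1),
                                cell, demo_spec)
  expect_length(omit_all$polygons, 0L)

  # determinism
  again <- simulate_labeller(truth, labeller_spec(skill = 1, seed = 1),
                             cell, demo_spec)
  expect_equal(length(again$polygons), length(perfect$polygons))
  expect_equal(again$polygons[[1]]$rings[[1]], perfect$polygons[[1]]$rings[[1]])
})

test_that("mean label quality decreases as boundary jitter grows", {
  l <- make_landscape(9, small_tile, demo_spec)
  truth <- landscape_crop_polygons(l)
  cell <- primary_cells_of(small_tile, demo_spec)[[34]]
  ref_polys <- fieldmapr:::clip_polys_bbox(truth, cell)
  ref <- annotation(ref_polys, "ref", cell)
  jitters <- c(0.3, 1.5, 4)
  mean_scores <- vapply(jitters, function(j) {
    mean(vapply(1:8, function(s) {
      cand <- simulate_labeller(truth,
                                labeller_spec(jitter_px = j,
                                              omission_rate = 0,
                                              commission_rate = 0,
                                              seed = 100 + s),
                                cell, demo_spec)
      score_assignment(cand, ref, cell, demo_spec)$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_scores) < 0))
})
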