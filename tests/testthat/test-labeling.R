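# Annotation rasterization, the five-component quality score, consensus
# fusion and its Bayes risk, and the task scheduler.

cellA <- cell_ref("primary", 3, 4, demo_spec)  # 20 x 20 pixel window
bA <- cellA$bounds

test_that("rasterization follows the pixel-center rule", {
  s <- demo_spec$primary_size
  full <- sq_poly(bA["lon0"] - s / 10, bA["lat0"] - s / 10, 1.2 * s)
  m_full <- rasterize_annotation(list(full), cellA, demo_spec)
  expect_equal(sum(m_full), 400L)  # every pixel of the cell window

  expect_equal(sum(rasterize_annotation(list(), cellA, demo_spec)), 0L)

  # axis-aligned half-cell rectangle: exactly half the pixels under the
  # center rule, verified against a brute-force center test
  half <- polygon_geom(rbind(
    c(bA["lon0"], bA["lat0"]), c(bA["lon0"] + s / 2, bA["lat0"]),
    c(bA["lon0"] + s / 2, bA["lat1"]), c(bA["lon0"], bA["lat1"])))
  m_half <- rasterize_annotation(list(half), cellA, demo_spec)
  expect_equal(sum(m_half), 200L)
  geom <- raster_geom(cellA, demo_spec)
  ctr <- pixel_centers(geom)
  brute <- outer(ctr$lat, ctr$lon, function(la, lo)
    lo > bA["lon0"] & lo < bA["lon0"] + s / 2 &
      la > bA["lat0"] & la < bA["lat1"])
  expect_equal(unname(m_half == 1L), unname(brute))
})

test_that("assignment scoring rewards identity and penalizes fragmentation", {
  s <- demo_spec$primary_size
  one <- sq_poly(bA["lon0"] + 0.2 * s, bA["lat0"] + 0.2 * s, 0.5 * s)
  idsc <- score_assignment(list(one), list(one), cellA, demo_spec)
  expect_equal(unname(idsc$components), rep(1, 5))
  expect_equal(idsc$score, 1)

  # both empty: all components 1 by convention
  empty <- score_assignment(list(), list(), cellA, demo_spec)
  expect_equal(empty$score, 1)

  # same region split in two: F = 1/2, I stays ~1, score drops below 1
  left <- polygon_geom(rbind(
    c(bA["lon0"] + 0.2 * s, bA["lat0"] + 0.2 * s),
    c(bA["lon0"] + 0.45 * s, bA["lat0"] + 0.2 * s),
    c(bA["lon0"] + 0.45 * s, bA["lat0"] + 0.7 * s),
    c(bA["lon0"] + 0.2 * s, bA["lat0"] + 0.7 * s)))
  right <- polygon_geom(rbind(
    c(bA["lon0"] + 0.45 * s, bA["lat0"] + 0.2 * s),
    c(bA["lon0"] + 0.7 * s, bA["lat0"] + 0.2 * s),
    c(bA["lon0"] + 0.7 * s, bA["lat0"] + 0.7 * s),
    c(bA["lon0"] + 0.45 * s, bA["lat0"] + 0.7 * s)))
  split_sc <- score_assignment(list(left, right), list(one), cellA, demo_spec)
  expect_equal(unname(split_sc$components["F"]), 0.5)
  expect_gt(unname(split_sc$components["I"]), 0.97)
  expect_lt(split_sc$score, 1)

  expect_error(score_assignment(list(one), list(one), cellA, demo_spec,
                                beta = c(0.5, 0.5, 0.5, 0, 0)), "sum to 1")
})

test_that("score components stay in [0, 1] on randomized polygon pairs", {
  set.seed(31)
  s <- demo_spec$primary_size
  mid <- c(bA["lon0"] + s / 2, bA["lat0"] + s / 2)
  for (i in 1:12) {
    n_c <- sample(0:3, 1); n_r <- sample(0:3, 1)
    cand <- lapply(seq_len(n_c), function(k)
      random_poly(mid[1] + runif(1, -s, s), mid[2] + runif(1, -s, s),
                  runif(1, 0.1, 0.6) * s))
    ref <- lapply(seq_len(n_r), function(k)
      random_poly(mid[1] + runif(1, -s, s), mid[2] + runif(1, -s, s),
                  runif(1, 0.1, 0.6) * s))
    sc <- score_assignment(cand, ref, cellA, demo_spec)
    expect_true(all(sc$components >= 0 & sc$components <= 1))
    expect_gte(sc$score, 0); expect_lte(sc$score, 1)
  }
})

test_that("labeller weight is the mean AOI score with a 0.5 prior", {
  p <- labeller_profile("w1")
  expect_equal(labeller_weight(p, "aoi1"), 0.5)
  p <- record_score(p, "aoi1", 0.8)
  expect_equal(labeller_weight(p, "aoi1"), 0.8)
  p <- record_score(p, "aoi1", 0.6)
  expect_equal(labeller_weight(p, "aoi1"), 0.7)
  expect_equal(labeller_weight(p, "aoi2"), 0.5)  # history is per AOI
})

test_that("consensus fusion is the normalized weighted vote", {
  m1 <- matrix(c(1, 0, 1, 0), 2)
  m0 <- matrix(0L, 2, 2)
  mAll <- matrix(1L, 2, 2)

  # degenerate weighting: consensus equals the only weighted labeller
  cw <- merge_consensus(list(m1, m0, mAll, m0), c(1, 0, 0, 0))
  expect_equal(cw$p, m1 * 1)

  # unanimity gives p = 1 regardless of positive weights
  cu <- merge_consensus(list(mAll, mAll, mAll, mAll), c(0.9, 0.3, 0.5, 0.2))
  expect_true(all(cu$p == 1))
  expect_equal(cu$risk, 0)

  # worked example: weights (0.8, 0.6, 0.7, 0.5), labels (1, 1, 0, 1)
  one <- matrix(1L, 1, 1); zero <- matrix(0L, 1, 1)
  cx <- merge_consensus(list(one, one, zero, one), c(0.8, 0.6, 0.7, 0.5))
  expect_equal(cx$p[1, 1], 1.9 / 2.6, tolerance = 1e-12)
  expect_equal(cx$class[1, 1], 1L)

  # tie p = 0.5 resolves to non-field
  ct <- merge_consensus(list(one, zero), c(0.5, 0.5))
  expect_equal(ct$class[1, 1], 0L)

  expect_error(merge_consensus(list(m1, m0), c(0, 0)), "zero")
})

test_that("raising a labeller's weight pulls disputed pixels toward their label", {
  one <- matrix(1L, 1, 1); zero <- matrix(0L, 1, 1)
  w <- c(0.4, 0.5, 0.6, 0.5)
  p_path <- vapply(seq(0.1, 1, by = 0.1), function(w1)
    merge_consensus(list(one, zero, zero, one), c(w1, w[2:4]))$p[1, 1],
    numeric(1))
  expect_true(all(diff(p_path) > 0))
})

test_that("Bayes risk hits its endpoints and is label-symmetric", {
  expect_equal(bayes_risk(matrix(c(0, 1, 1, 0), 2)), 0)
  expect_equal(bayes_risk(matrix(0.5, 3, 3)), 1)
  expect_equal(bayes_risk(matrix(1.9 / 2.6, 1)), 0.5385, tolerance = 1e-4)
  p <- matrix(runif(25), 5)
  expect_equal(bayes_risk(p), bayes_risk(1 - p))

  # risk is 0 iff all masks agree (under positive weights)
  m <- matrix(c(1, 0, 1, 1), 2)
  same <- merge_consensus(list(m, m, m, m), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(same$risk, 0)
  m2 <- m; m2[1, 1] <- 0L
  diff_ <- merge_consensus(list(m, m, m2, m), c(0.9, 0.8, 0.7, 0.6))
  expect_gt(diff_$risk, 0)
})

test_that("the scheduler interleaves QA at 1 per 5 mapped and caps tasks", {
  q <- task_queue(training_ids = paste0("t", 1:20),
                  qa_ids = paste0("qa", 1:5))
  served <- character(0)
  for (i in 1:12) {
    nx <- schedule_next(q, "alice")
    q <- nx$queue
    served <- c(served, nx$task$cell_id)
  }
  qa_positions <- grep("^qa", served)
  expect_equal(qa_positions, c(6L, 12L))  # 2 QA within 12 served, every 6th
  expect_equal(sum(!grepl("^qa", served)), 10L)
  expect_equal(anyDuplicated(served[!grepl("^qa", served)]), 0L)

  # a training task completes after 4 distinct labellers
  q2 <- task_queue(training_ids = "t1")
  for (lab in c("a", "b", "c")) q2 <- schedule_next(q2, lab)$queue
  expect_length(completed_training_tasks(q2), 0L)
  q2 <- schedule_next(q2, "d")$queue
  expect_equal(completed_training_tasks(q2), "t1")

  # exhaustion raises a typed condition
  expect_error(schedule_next(q2, "e"), class = "fieldmapr_queue_exhausted")
})
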