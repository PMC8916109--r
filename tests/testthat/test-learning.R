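# Feature extraction, the balanced forest, evaluation metrics, uncertainty
# scoring and active-site selection.

test_that("feature extraction yields 24 deterministic bands", {
  set.seed(41)
  g <- array(runif(16 * 16 * 4), c(16, 16, 4))
  d <- array(runif(16 * 16 * 4), c(16, 16, 4))
  f <- extract_features(g, d)
  expect_equal(dim(f)[3], 24L)
  expect_identical(f, extract_features(g, d))

  # constant input: mean band constant, sd band zero
  gc <- array(0.3, c(8, 8, 4)); dc <- array(0.6, c(8, 8, 4))
  fc <- extract_features(gc, dc)
  expect_equal(unname(fc[, , 9]), matrix(0.3, 8, 8))
  expect_true(all(abs(fc[, , 17:24]) < 1e-6))

  # unit impulse spreads to 1/121 over the 11 x 11 mean window
  gi <- array(0, c(15, 15, 4)); gi[8, 8, 1] <- 1
  fi <- extract_features(gi, array(0, c(15, 15, 4)))
  expect_equal(unname(fi[8, 8, 9]), 1 / 121)
  expect_equal(unname(fi[8, 14, 9]), 0)  # outside the 11 x 11 reach
})

test_that("moving windows match a brute-force oracle with reflect padding", {
  set.seed(42)
  m <- matrix(runif(32 * 32), 32)
  for (k in c(5L, 11L)) {
    got_mean <- window_mean(m, k)
    got_sd <- window_sd(m, k)
    h <- (k - 1L) / 2L
    refl_idx <- function(i, n) {
      i <- ifelse(i < 1, 1 - i, i)
      ifelse(i > n, 2 * n + 1 - i, i)
    }
    for (pt in list(c(1, 1), c(3, 30), c(16, 16), c(32, 1))) {
      ii <- refl_idx(pt[1] + (-h:h), 32)
      jj <- refl_idx(pt[2] + (-h:h), 32)
      vals <- m[ii, jj]
      expect_equal(got_mean[pt[1], pt[2]], mean(vals), tolerance = 1e-12)
      expect_equal(got_sd[pt[1], pt[2]],
                   sqrt(mean((vals - mean(vals))^2)), tolerance = 1e-12)
    }
  }
})

test_that("training assembly balances classes deterministically", {
  set.seed(43)
  x <- matrix(rnorm(1250 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0, 1), c(1000, 250))
  bal <- assemble_training(y, x, seed = 5)
  expect_equal(unname(table(bal$y)), c(250L, 250L), ignore_attr = TRUE)
  expect_identical(bal$idx, assemble_training(y, x, seed = 5)$idx)
  expect_false(identical(bal$idx, assemble_training(y, x, seed = 6)$idx))

  even <- assemble_training(rep(c(0, 1), 10), x[1:20, ], seed = 1)
  expect_equal(length(even$idx), 20L)
  expect_error(assemble_training(rep(1, 10), x[1:10, ], seed = 1),
               "cannot balance")
})

test_that("the forest is reproducible and vote probabilities are 60ths", {
  set.seed(44)
  n <- 300
  x <- cbind(f1 = c(rnorm(n / 2), rnorm(n / 2, 2.5)), f2 = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  sampl <- assemble_training(y, x, seed = 1)
  m1 <- fit_classifier(sampl, seed = 9)
  m2 <- fit_classifier(sampl, seed = 9)
  expect_equal(m1$num_trees, 60L)
  expect_equal(m1$max_depth, 15L)
  probe <- cbind(f1 = seq(-2, 4, length.out = 50), f2 = rep(0, 50))
  p1 <- predict_probabilities(m1, probe)
  p2 <- predict_probabilities(m2, probe)
  expect_identical(p1, p2)
  expect_true(all(abs(p1 * 60 - round(p1 * 60)) < 1e-9))
  expect_true(all(p1 >= 0 & p1 <= 1))

  # linearly separable features are learned perfectly
  wide <- cbind(f1 = c(rep(-3, 50), rep(3, 50)), f2 = rnorm(100))
  ms <- fit_classifier(assemble_training(rep(c(0, 1), each = 50), wide,
                                         seed = 1), seed = 1)
  ptr <- predict_probabilities(ms, wide)
  expect_equal(as.integer(ptr > 0.5), rep(c(0L, 1L), each = 50))

  # NA feature rows propagate to NA predictions
  probe_na <- probe; probe_na[3, 1] <- NA
  expect_true(is.na(predict_probabilities(m1, probe_na)[3]))
  expect_error(predict_probabilities(m1, cbind(z = 1:3)), "feature")
})

test_that("evaluation metrics match direct confusion arithmetic", {
  perfect <- evaluate_predictions(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(perfect), c(1, 1, 1, 0))

  allpos <- evaluate_predictions(rep(0.9, 100), rep(c(1, 0), 50))
  expect_equal(unname(allpos["accuracy"]), 0.5)
  expect_equal(unname(allpos["fpr"]), 1)

  # TP=30, FP=20, FN=10, TN=40
  y <- rep(c(1, 0, 1, 0), c(30, 20, 10, 40))
  p <- rep(c(0.9, 0.9, 0.1, 0.1), c(30, 20, 10, 40))
  m <- evaluate_predictions(p, y)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(m["fpr"]), 1 / 3)

  expect_error(evaluate_predictions(c(0.2, 0.8), c(1, 1)), "both classes")

  # AUC rank statistic agrees with an independent implementation
  skip_if_not_installed("pROC")
  set.seed(45)
  y2 <- rbinom(200, 1, 0.4)
  y2[1:2] <- c(0, 1)
  p2 <- runif(200) + 0.3 * y2
  got <- unname(evaluate_predictions(p2, y2)["auc"])
  ref <- as.numeric(pROC::auc(pROC::roc(y2, p2, quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("site uncertainty hits the documented endpoints and bounds", {
  expect_equal(site_uncertainty(matrix(0.5, 10, 10))$q, 0)
  hard <- site_uncertainty(matrix(rep(c(0, 1), 50), 10, 10))
  expect_equal(hard$q, 25)  # 0.25 per pixel at p in {0, 1}, n = 100
  expect_equal(site_uncertainty(c(0.1, 0.5, 0.9))$q, 0.32)
  expect_error(site_uncertainty(matrix(NA_real_, 2, 2)), "no valid")

  # 0 <= Q <= 0.25 n over random inputs; subsetting is seeded
  set.seed(46)
  for (i in 1:10) {
    p <- matrix(runif(900), 30)
    u <- site_uncertainty(p, n_sample = 200, seed = i)
    expect_equal(u$n, 200L)
    expect_gte(u$q, 0); expect_lte(u$q, 0.25 * u$n)
    expect_equal(u$q, site_uncertainty(p, n_sample = 200, seed = i)$q)
  }
})

test_that("active-site selection draws from the most uncertain 30%", {
  q <- setNames(seq(0.01, 1, length.out = 100), paste0("c", 1:100))
  low30 <- names(sort(q))[1:30]
  sel <- select_active_sites(q, 10, seed = 2)
  expect_length(sel, 10L)
  expect_true(all(sel %in% low30))
  expect_identical(sel, select_active_sites(q, 10, seed = 2))

  all30 <- select_active_sites(q, 30, seed = 3)
  expect_setequal(all30, low30)
  over <- select_active_sites(q, 50, seed = 3)
  expect_setequal(over, low30)
  expect_error(select_active_sites(numeric(0), 5), "empty")
})

test_that("a zero-iteration loop reduces to plain train/evaluate", {
  inst <- demo_learning_instance(12)
  r0 <- run_active_loop(inst$sites, inst$starter_ids, inst$pool_ids,
                        inst$validation_ids, inst$label_fun,
                        max_iterations = 0L, seed = 3,
                        max_px_per_class = Inf)
  expect_equal(nrow(r0$log), 1L)
  expect_equal(r0$log$n_train_cells, length(inst$starter_ids))

  # direct train/evaluate with the same seeds gives identical metrics
  tr <- fieldmapr:::stack_site_pixels(inst$sites, inst$starter_ids,
                                      lapply(setNames(inst$starter_ids,
                                                      inst$starter_ids),
                                             inst$label_fun))
  bal <- assemble_training(tr$y, tr$x, seed = derive_seed(3, "it0"))
  mod <- fit_classifier(bal, seed = derive_seed(3, "fit0"))
  val <- fieldmapr:::stack_site_pixels(inst$sites, inst$validation_ids, NULL)
  m <- evaluate_predictions(predict_probabilities(mod, val$x), val$y)
  expect_equal(r0$log$f1, unname(m["f1"]))
  expect_equal(r0$log$accuracy, unname(m["accuracy"]))
})
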