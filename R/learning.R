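# Feature extraction, balanced random-forest cropland classification,
# prediction uncertainty, and the active-learning loop with its two
# controlled experiments (active vs random site selection; consensus vs
# best vs worst labeller training sets).

FEATURE_WINDOW_MEAN <- 11L
FEATURE_WINDOW_SD <- 5L

#' Extract the 24-band feature stack from a seasonal composite pair
#'
#' Band order: the 8 raw bands (growing blue, green, red, nir, then dry
#' likewise), their 11 x 11 moving-window means, and their 5 x 5
#' moving-window population standard deviations. Windows use reflect
#' padding at tile edges.
#'
#' @param growing,dry `seasonal_composite`s (or bare `[row, col, 4]`
#'   arrays) on the same grid.
#' @return `[row, col, 24]` array with named bands.
#' @export
extract_features <- function(growing, dry) {
  g <- if (inherits(growing, "seasonal_composite")) growing$values else growing
  d <- if (inherits(dry, "seasonal_composite")) dry$values else dry
  if (!identical(dim(g)[1:2], dim(d)[1:2])) stop("composites not co-registered")
  if (dim(g)[3] != 4L || dim(d)[3] != 4L) stop("composites must have 4 bands")
  raw <- array(0, c(dim(g)[1], dim(g)[2], 8L))
  raw[, , 1:4] <- g
  raw[, , 5:8] <- d
  out <- array(0, c(dim(g)[1], dim(g)[2], 24L))
  out[, , 1:8] <- raw
  for (b in 1:8) {
    out[, , 8L + b] <- window_mean(raw[, , b], FEATURE_WINDOW_MEAN)
    out[, , 16L + b] <- window_sd(raw[, , b], FEATURE_WINDOW_SD)
  }
  nm <- c(outer(BAND_NAMES, c("growing", "dry"),
                function(b, s) paste(s, b, sep = "_")))
  dimnames(out) <- list(NULL, NULL, c(nm, paste0("mean_", nm),
                                      paste0("sd_", nm)))
  out
}

feature_table <- function(features, mask = NULL) {
  d <- dim(features)
  m <- matrix(features, d[1] * d[2], d[3])
  colnames(m) <- dimnames(features)[[3]]
  if (!is.null(mask)) m <- m[as.vector(mask), , drop = FALSE]
  m
}

#' Assemble a balanced training sample
#'
#' Downsamples the majority class to the minority-class count.
#'
#' @param labels integer/logical vector of pixel labels (1 = field).
#' @param features matrix of pixel features (rows align with `labels`).
#' @param seed integer seed controlling the downsample.
#' @return list `x` (feature matrix), `y` (factor labels), `idx` (row
#'   indices kept).
#' @export
assemble_training <- function(labels, features, seed = 1L) {
  y <- as.integer(labels > 0)
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0))
    stop("cannot balance: a class is absent from the labels")
  n <- min(length(i0), length(i1))
  set.seed(derive_seed(seed, "balance"))
  keep <- c(if (length(i0) > n) sample(i0, n) else i0,
            if (length(i1) > n) sample(i1, n) else i1)
  keep <- sort(keep)
  list(x = features[keep, , drop = FALSE],
       y = factor(y[keep], levels = c(0, 1)), idx = keep)
}

#' Fit the cropland random-forest classifier
#'
#' A classification forest with the production settings: 60 trees, maximum
#' depth 15; predictions are soft votes (the fraction of trees voting
#' cropland). Single-threaded with a fixed seed, so refits on identical
#' inputs reproduce predictions exactly.
#'
#' @param sample list `x`, `y` as from [assemble_training()].
#' @param num_trees,max_depth hyperparameters.
#' @param seed integer seed.
#' @return object of class `cropland_model`.
#' @export
fit_classifier <- function(sample, num_trees = 60L, max_depth = 15L,
                           seed = 1L) {
  if (!nrow(sample$x) || nlevels(droplevels(sample$y)) < 2)
    stop("degenerate training sample: need both classes")
  df <- data.frame(sample$x, check.names = FALSE)
  df$.class <- sample$y
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, max.depth = max_depth,
    seed = derive_seed(seed, "forest"),
    num.threads = 1L, verbose = FALSE)
  structure(list(fit = fit, features = colnames(sample$x),
                 num_trees = num_trees, max_depth = max_depth, seed = seed),
            class = "cropland_model")
}

#' Predict per-pixel cropland probabilities
#'
#' Soft votes: the fraction of trees voting cropland, in `[0, 1]`.
#' `NA` feature rows (nodata pixels) propagate to `NA` probabilities.
#'
#' @param model a `cropland_model`.
#' @param features `[row, col, 24]` array or a feature matrix.
#' @return probability map shaped like the input (matrix for array input,
#'   vector for matrix input).
#' @export
predict_probabilities <- function(model, features) {
  is_arr <- length(dim(features)) == 3L
  m <- if (is_arr) feature_table(features) else features
  if (!identical(colnames(m), model$features))
    stop("feature names/order do not match the training features")
  ok <- stats::complete.cases(m)
  p <- rep(NA_real_, nrow(m))
  if (any(ok)) {
    votes <- predict(model$fit, data.frame(m[ok, , drop = FALSE],
                                           check.names = FALSE),
                     predict.all = TRUE, num.threads = 1L)$predictions
    crop_code <- match("1", model$fit$forest$levels)
    p[ok] <- rowMeans(votes == crop_code)
  }
  if (is_arr) matrix(p, dim(features)[1], dim(features)[2]) else p
}

#' Classification metrics against validation labels
#'
#' @param p predicted probabilities.
#' @param y true labels (1 = field).
#' @param threshold classification threshold.
#' @return named vector: `accuracy`, `auc` (Mann-Whitney rank statistic),
#'   `f1` (harmonic mean of precision and recall), `fpr`.
#' @export
evaluate_predictions <- function(p, y, threshold = 0.5) {
  keep <- !is.na(p) & !is.na(y)
  p <- p[keep]; y <- as.integer(y[keep] > 0)
  if (!length(p) || length(unique(y)) < 2)
    stop("validation set must contain both classes")
  pred <- as.integer(p > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  r <- rank(p)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(accuracy = acc, auc = auc, f1 = f1, fpr = fpr)
}

#' Site-level prediction uncertainty
#'
#' `Q = sum((p - 0.5)^2)` over a seeded random subset of the cell's
#' predicted pixels. Lower Q means probabilities cluster near 0.5, i.e. the
#' cell is harder for the classifier and more informative to label.
#'
#' @param p probability matrix (or vector) for the cell's pixels.
#' @param n_sample subset size (all pixels if fewer are available).
#' @param seed integer seed.
#' @return list `q`, `n` (pixels used).
#' @export
site_uncertainty <- function(p, n_sample = 1000L, seed = 1L) {
  v <- as.vector(p)
  v <- v[!is.na(v)]
  if (!length(v)) stop("cell has no valid predictions")
  if (length(v) > n_sample) {
    set.seed(derive_seed(seed, "qsample"))
    v <- v[sample.int(length(v), n_sample)]
  }
  list(q = sum((v - 0.5)^2), n = length(v))
}

#' Select sites for the next active-learning round
#'
#' Cells are ranked by ascending uncertainty score Q and `k` cells are
#' drawn uniformly at random from the most-uncertain 30% (a random draw
#' within the top block reduces spatial autocorrelation among selected
#' sites). If `k` exceeds the block, the whole block is returned.
#'
#' @param scores named numeric vector of Q values (names are cell ids).
#' @param k number of cells to select.
#' @param seed integer seed.
#' @param top_frac fraction of the ranking forming the candidate block.
#' @return character vector of selected cell ids.
#' @export
select_active_sites <- function(scores, k, seed = 1L, top_frac = 0.3) {
  if (!length(scores)) stop("empty candidate pool")
  pool <- names(sort(scores))[seq_len(ceiling(top_frac * length(scores)))]
  set.seed(derive_seed(seed, "select"))
  if (k >= length(pool)) return(sample(pool))
  sample(pool, k)
}

# --- active-learning harness -------------------------------------------------

#' Run the active-learning loop over labelled sites
#'
#' Each iteration trains a balanced forest on the labelled cells, evaluates
#' it against held-out validation cells, predicts the unlabelled pool,
#' ranks cells by uncertainty and requests labels for a new batch. Stops
#' after `max_iterations` or when the validation F1 gain drops below
#' `min_f1_gain`.
#'
#' @param sites a site table from [build_site_table()]: per-cell feature
#'   matrices and (for labelled cells) label vectors.
#' @param starter_ids,pool_ids,validation_ids character cell ids.
#' @param label_fun function(cell_id) -> 0/1 label vector for the cell's
#'   pixels (a simulated labeller or consensus; files in production).
#' @param k batch size per iteration.
#' @param max_iterations iteration cap.
#' @param min_f1_gain early-stop threshold on the F1 improvement.
#' @param selection `"active"` (uncertainty ranking) or `"random"`.
#' @param n_sample pixels per cell entering the Q sum.
#' @param num_trees,max_depth forest hyperparameters.
#' @param seed integer seed.
#' @param max_px_per_class cap on balanced training pixels per class.
#' @return list `log` (per-iteration data.frame), `model` (final
#'   `cropland_model`), `labelled_ids`, `prob` (named list of final
#'   probability matrices per pool/validation cell).
#' @export
run_active_loop <- function(sites, starter_ids, pool_ids, validation_ids,
                            label_fun, k = 10L, max_iterations = 3L,
                            min_f1_gain = 0.005, selection = "active",
                            n_sample = 1000L, num_trees = 60L,
                            max_depth = 15L, seed = 1L,
                            max_px_per_class = 2000L) {
  labelled <- starter_ids
  labels <- lapply(setNames(labelled, labelled), label_fun)
  pool <- setdiff(pool_ids, labelled)
  log <- list()
  model <- NULL
  prev_f1 <- -Inf
  for (iter in 0:max_iterations) {
    tr <- stack_site_pixels(sites, labelled, labels)
    bal <- assemble_training(tr$y, tr$x, seed = derive_seed(seed, paste0("it", iter)))
    if (nrow(bal$x) > 2L * max_px_per_class) {
      set.seed(derive_seed(seed, paste0("cap", iter)))
      keep <- sample.int(nrow(bal$x), 2L * max_px_per_class)
      bal$x <- bal$x[keep, , drop = FALSE]; bal$y <- bal$y[keep]
    }
    model <- fit_classifier(bal, num_trees = num_trees, max_depth = max_depth,
                            seed = derive_seed(seed, paste0("fit", iter)))
    val <- stack_site_pixels(sites, validation_ids, NULL)
    pv <- predict_probabilities(model, val$x)
    metrics <- evaluate_predictions(pv, val$y)
    log[[length(log) + 1L]] <- data.frame(
      iteration = iter, n_train_cells = length(labelled),
      accuracy = metrics["accuracy"], auc = metrics["auc"],
      f1 = metrics["f1"], fpr = metrics["fpr"], row.names = NULL)
    if (iter == max_iterations) break
    if (metrics["f1"] - prev_f1 < min_f1_gain && iter > 0) break
    prev_f1 <- metrics["f1"]
    if (!length(pool)) break
    if (selection == "active") {
      q <- vapply(pool, function(id) {
        pp <- predict_probabilities(model, sites$features[[id]])
        site_uncertainty(pp, n_sample = n_sample,
                         seed = derive_seed(seed, id))$q
      }, numeric(1))
      batch <- select_active_sites(q, min(k, length(pool)),
                                   seed = derive_seed(seed, paste0("sel", iter)))
    } else {
      set.seed(derive_seed(seed, paste0("rand", iter)))
      batch <- sample(pool, min(k, length(pool)))
    }
    for (id in batch) labels[[id]] <- label_fun(id)
    labelled <- c(labelled, batch)
    pool <- setdiff(pool, batch)
  }
  list(log = do.call(rbind, log), model = model, labelled_ids = labelled,
       validation = setNames(as.numeric(metrics), names(metrics)))
}

#' Build a site table from composites over a tile
#'
#' Precomputes per-primary-cell feature matrices (and truth label vectors
#' when a truth mask is supplied) for the learning harness.
#'
#' @param features `[row, col, 24]` feature array of the tile/domain.
#' @param cells list of primary-level [cell_ref()]s within the domain.
#' @param geom the domain [raster_geom()].
#' @param spec a [grid_spec()].
#' @param truth optional 0/1 truth raster aligned with `features`.
#' @return list: `features` (named list of per-cell pixel-feature
#'   matrices), `truth` (named list of label vectors or NULL), `window`
#'   (named list of row/col index ranges).
#' @export
build_site_table <- function(features, cells, geom, spec, truth = NULL) {
  ft <- list(); tr <- list(); win <- list()
  for (cell in cells) {
    id <- cell_id(cell)
    w <- cell_pixel_window(cell, geom, spec)
    sub <- features[w$rows, w$cols, , drop = FALSE]
    ft[[id]] <- feature_table(sub)
    win[[id]] <- w
    if (!is.null(truth)) tr[[id]] <- as.vector(truth[w$rows, w$cols])
  }
  list(features = ft, truth = if (is.null(truth)) NULL else tr, window = win)
}

cell_pixel_window <- function(cell, geom, spec) {
  b <- cell$bounds
  px <- geom$px
  c0 <- round((b["lon0"] - geom$bounds["lon0"]) / px)
  r0 <- round((geom$bounds["lat1"] - b["lat1"]) / px)
  n <- round((b["lon1"] - b["lon0"]) / px)
  list(rows = (r0 + 1):(r0 + n), cols = (c0 + 1):(c0 + n))
}

stack_site_pixels <- function(sites, ids, labels) {
  xs <- lapply(ids, function(id) sites$features[[id]])
  x <- do.call(rbind, xs)
  y <- if (is.null(labels)) {
    unlist(lapply(ids, function(id) sites$truth[[id]]), use.names = FALSE)
  } else {
    unlist(lapply(ids, function(id) labels[[id]]), use.names = FALSE)
  }
  list(x = x, y = y)
}

#' Run the two label-selection experiments
#'
#' Experiment A retrains with actively vs randomly selected sites under
#' identical seeds and reports the per-iteration metric deltas. Experiment
#' B trains on three label sets for the same cells (lowest-scoring
#' labeller, highest-scoring labeller, quality-weighted consensus) and
#' compares validation metrics. Both are averaged over seeds.
#'
#' @param make_instance function(seed) returning a list with `sites`,
#'   `starter_ids`, `pool_ids`, `validation_ids`, `label_fun` (truth or
#'   consensus labels), and for experiment B `label_funs`, a named list
#'   (`consensus`, `best`, `worst`) of label providers.
#' @param seeds integer vector of replicate seeds.
#' @param which `"active_vs_random"`, `"label_quality"`, or both.
#' @param ... passed through to [run_active_loop()].
#' @return list of data.frames `active_vs_random` (mean final metrics per
#'   arm) and `label_quality` (mean metrics per label set).
#' @export
run_experiments <- function(make_instance, seeds = 1:10,
                            which = c("active_vs_random", "label_quality"),
                            ...) {
  out <- list()
  if ("active_vs_random" %in% which) {
    rows <- list()
    for (s in seeds) {
      inst <- make_instance(s)
      for (arm in c("active", "random")) {
        r <- run_active_loop(inst$sites, inst$starter_ids, inst$pool_ids,
                             inst$validation_ids, inst$label_fun,
                             selection = arm, seed = s,
                             min_f1_gain = -Inf, ...)
        fin <- tail(r$log, 1)
        rows[[length(rows) + 1L]] <- cbind(seed = s, arm = arm, fin)
      }
    }
    df <- do.call(rbind, rows)
    out$active_vs_random <- df
  }
  if ("label_quality" %in% which) {
    rows <- list()
    for (s in seeds) {
      inst <- make_instance(s)
      for (set in names(inst$label_funs)) {
        lf <- inst$label_funs[[set]]
        tr_ids <- inst$starter_ids
        labels <- lapply(setNames(tr_ids, tr_ids), lf)
        tr <- stack_site_pixels(inst$sites, tr_ids, labels)
        bal <- assemble_training(tr$y, tr$x, seed = derive_seed(s, set))
        model <- fit_classifier(bal, seed = derive_seed(s, set))
        val <- stack_site_pixels(inst$sites, inst$validation_ids, NULL)
        pv <- predict_probabilities(model, val$x)
        m <- evaluate_predictions(pv, val$y)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = s, label_set = set, accuracy = m["accuracy"],
          auc = m["auc"], f1 = m["f1"], fpr = m["fpr"], row.names = NULL)
      }
    }
    out$label_quality <- do.call(rbind, rows)
  }
  out
}
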