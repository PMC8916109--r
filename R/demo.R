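# Desk-scale study harness: wires the synthetic landscape, compositing,
# labelling, learning and segmentation stages together at a reduced pixel
# size (0.00025 degrees, ~28 m) so a full tile is 200 x 200 pixels and a
# primary cell 20 x 20. All stage logic is identical to production scale;
# only the grid resolution and batch sizes shrink.

#' Demo grid specification
#' @param pixel_size pixel edge, degrees.
#' @return a [grid_spec()] with 0.05-degree tiles and 0.005-degree primary
#'   cells.
#' @export
demo_grid_spec <- function(pixel_size = 0.00025) {
  grid_spec(pixel_size = pixel_size)
}

#' Default season windows for the demo year
#' @return list of growing (May-September) and dry (December-February)
#'   [season_window()]s.
#' @export
demo_seasons <- function() {
  list(growing = season_window("growing", "2018-05-01", "2018-09-30"),
       dry = season_window("dry", "2018-12-01", "2019-02-28"))
}

#' Default acquisition dates for the demo year
#' @param n_per_season dates per season.
#' @return vector of `Date`s spanning both season windows.
#' @export
demo_dates <- function(n_per_season = 8L) {
  c(seq(as.Date("2018-05-10"), as.Date("2018-09-20"),
        length.out = n_per_season),
    seq(as.Date("2018-12-10"), as.Date("2019-02-20"),
        length.out = n_per_season))
}

#' Simulate the labelling stage for a set of cells
#'
#' Each labeller first completes QA (accuracy-assessment) cells scored
#' against the reference polygons, building the quality history that sets
#' their consensus weight; every training cell then receives one
#' assignment per labeller and the four masks are fused into a consensus
#' label.
#'
#' @param landscape a [make_landscape()] result.
#' @param cells list of primary-level [cell_ref()]s to label.
#' @param labellers list of [labeller_spec()]s.
#' @param spec a [grid_spec()].
#' @param qa_cells list of QA [cell_ref()]s (reference = truth polygons).
#' @param aoi AOI id for the score history.
#' @param beta score-component weights, passed to [score_assignment()].
#' @return list: `consensus` (named list of `consensus_label`), `weights`,
#'   `profiles`, `masks` (per cell, list of the four labeller masks),
#'   `scores` (data.frame of QA scores).
#' @export
simulate_labelling <- function(landscape, cells, labellers, spec,
                               qa_cells = NULL, aoi = "aoi1",
                               beta = default_score_weights()) {
  truth <- landscape$polygons[landscape$cover == "cropland"]
  profiles <- list(); score_rows <- list()
  for (li in seq_along(labellers)) {
    lspec <- labellers[[li]]
    id <- paste0("labeller", li)
    prof <- labeller_profile(id)
    for (qc in qa_cells %||% list()) {
      cand <- simulate_labeller(truth, lspec, qc, spec)
      ref <- annotation(clip_polys_bbox(truth, qc), "reference", qc)
      sc <- score_assignment(cand, ref, qc, spec, beta = beta)
      prof <- record_score(prof, aoi, sc)
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        labeller_id = id, cell_id = cell_id(qc), score = sc$score)
    }
    profiles[[id]] <- prof
  }
  weights <- vapply(profiles, labeller_weight, numeric(1), aoi = aoi)
  consensus <- list(); masks <- list()
  for (cell in cells) {
    cid <- cell_id(cell)
    ms <- lapply(seq_along(labellers), function(li) {
      ann <- simulate_labeller(truth, labellers[[li]], cell, spec)
      rasterize_annotation(ann, cell, spec)
    })
    masks[[cid]] <- ms
    consensus[[cid]] <- merge_consensus(ms, weights)
  }
  list(consensus = consensus, weights = weights, profiles = profiles,
       masks = masks,
       scores = if (length(score_rows)) do.call(rbind, score_rows) else NULL)
}

clip_polys_bbox <- function(polys, cell) {
  b <- cell$bounds
  keep <- vapply(polys, function(p) {
    r <- p$rings[[1]]
    !(max(r[, 1]) < b["lon0"] || min(r[, 1]) >= b["lon1"] ||
        max(r[, 2]) < b["lat0"] || min(r[, 2]) >= b["lat1"])
  }, logical(1))
  polys[keep]
}

#' Build a complete demo learning instance
#'
#' Generates a landscape over one tile, renders and composites both
#' seasons, extracts the 24-band features, and splits the tile's primary
#' cells into starter, pool and validation sets. Truth labels come from
#' the landscape; optionally a panel of simulated labellers provides
#' consensus / best / worst label sets.
#'
#' @param seed integer seed.
#' @param spec a [grid_spec()] (demo default).
#' @param n_starter,n_validation cell counts (remaining cells form the
#'   active-learning pool).
#' @param with_labellers when TRUE, attach `label_funs` built from a
#'   4-labeller panel of decreasing skill (1.0, 0.7, 0.6, 0.5).
#' @param crop_fraction target cropland fraction.
#' @param n_qa QA cells used to score the panel.
#' @return list consumable by [run_active_loop()] / [run_experiments()]:
#'   `sites`, `starter_ids`, `pool_ids`, `validation_ids`, `label_fun`,
#'   optionally `label_funs`, plus `landscape`, `features`, `prob_geom`,
#'   `spec`, `tile`.
#' @export
demo_learning_instance <- function(seed, spec = demo_grid_spec(),
                                   n_starter = 20L, n_validation = 20L,
                                   with_labellers = FALSE,
                                   crop_fraction = 0.3, n_qa = 4L) {
  tile <- cell_ref("tile", 0, 0, spec)
  landscape <- make_landscape(seed, tile, spec,
                              params = list(crop_fraction = crop_fraction))
  seasons <- demo_seasons()
  rt <- render_time_series(landscape, demo_dates(),
                           atmosphere = list(seed = derive_seed(seed, "atm")))
  growing <- composite_tile(rt$stack, seasons$growing)
  dry <- composite_tile(rt$stack, seasons$dry)
  features <- extract_features(growing, dry)
  cells <- primary_cells_of(tile, spec)
  geom <- landscape$geom
  sites <- build_site_table(features, cells, geom, spec,
                            truth = landscape$truth_mask)
  ids <- names(sites$features)
  set.seed(derive_seed(seed, "split"))
  ord <- sample(ids)
  starter <- ord[seq_len(n_starter)]
  validation <- ord[n_starter + seq_len(n_validation)]
  pool <- setdiff(ids, c(starter, validation))
  out <- list(sites = sites, starter_ids = starter, pool_ids = pool,
              validation_ids = validation,
              label_fun = function(id) sites$truth[[id]],
              landscape = landscape, features = features,
              composites = list(growing = growing, dry = dry),
              spec = spec, tile = tile, geom = geom, seed = seed)
  if (with_labellers) {
    skills <- c(1.0, 0.7, 0.6, 0.5)
    panel <- lapply(seq_along(skills), function(i)
      labeller_spec(skill = skills[i], seed = derive_seed(seed, paste0("lab", i))))
    qa <- lapply(sample(seq_along(cells), n_qa), function(i) cells[[i]])
    train_cells <- lapply(starter, parse_cell_id, spec = spec)
    lab <- simulate_labelling(landscape, train_cells, panel, spec,
                              qa_cells = qa)
    rank_w <- order(lab$weights)  # ascending: worst first
    out$labelling <- lab
    out$label_funs <- list(
      consensus = function(id) as.vector(lab$consensus[[id]]$class),
      best = function(id)
        as.vector(lab$masks[[id]][[rank_w[length(rank_w)]]]),
      worst = function(id) as.vector(lab$masks[[id]][[rank_w[1]]]))
  }
  out
}

#' Segment a demo instance into field polygons
#'
#' Trains the classifier on a cell sample, predicts the full-tile
#' probability map, and runs the five segmentation steps (edge synthesis,
#' compact watershed, region merging, probability filtering, refinement).
#'
#' @param inst a [demo_learning_instance()].
#' @param n_train_cells training cells for the "well-trained" model.
#' @param n_segments watershed segment count for the tile.
#' @param merge_threshold region-merging color-distance threshold.
#' @return list: `fields` (`field_set`), `prob` (matrix), `segments`,
#'   `merged`, `model`.
#' @export
demo_segmentation_run <- function(inst, n_train_cells = 50L,
                                  n_segments = 625L,
                                  merge_threshold = 0.05) {
  ids <- names(inst$sites$features)
  set.seed(derive_seed(inst$seed, "segtrain"))
  train_ids <- sample(ids, min(n_train_cells, length(ids)))
  tr <- stack_site_pixels(inst$sites, train_ids, NULL)
  bal <- assemble_training(tr$y, tr$x, seed = inst$seed)
  model <- fit_classifier(bal, seed = inst$seed)
  prob <- predict_probabilities(model, inst$features)
  edges <- compute_edge_image(inst$composites$dry, prob)
  segments <- initial_watershed(edges, n_segments = n_segments)
  bands <- inst$composites$dry$values[, , 2:4, drop = FALSE]
  merged <- merge_regions(segments, bands, threshold = merge_threshold)
  fields <- filter_by_probability(merged, prob, inst$geom,
                                  tile_id = cell_id(inst$tile))
  fields <- refine_polygons(fields, tolerance = 0.5,
                            pixel_size = inst$spec$pixel_size)
  list(fields = fields, prob = prob, segments = segments, merged = merged,
       model = model)
}

#' Intersection-over-union of recovered fields vs the true cropland mask
#' @param fields a `field_set`.
#' @param landscape the [make_landscape()] truth.
#' @return scalar IoU of the rasterized field union against the truth mask.
#' @export
field_recovery_iou <- function(fields, landscape) {
  rec <- rasterize_polygons(fields$polygons, landscape$geom)
  tp <- sum(rec == 1 & landscape$truth_mask == 1)
  un <- sum(rec == 1 | landscape$truth_mask == 1)
  if (un == 0) return(1)
  tp / un
}
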