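# Configuration-driven orchestration: fixtures -> compositing -> labelling
# -> active learning -> segmentation -> assessment, with per-stage seeds
# derived from one global seed and a JSON manifest of hashed artifacts.

#' Load a pipeline configuration
#'
#' @param path YAML file; see `inst/extdata/demo_config.yaml` for the
#'   bundled demo. Missing blocks fall back to demo defaults except the
#'   required `seed` and `out_dir`.
#' @return validated config list.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname load_pipeline_config
#' @param cfg config list.
#' @export
validate_pipeline_config <- function(cfg) {
  for (block in c("seed", "out_dir"))
    if (is.null(cfg[[block]])) stop("config missing required block: ", block)
  defaults <- list(
    grid = list(pixel_size = 0.00025),
    fixtures = list(crop_fraction = 0.3, n_dates_per_season = 8),
    labelling = list(skills = c(1.0, 0.7, 0.6, 0.5), n_qa = 4),
    learning = list(n_starter = 20, n_validation = 20, k = 10,
                    max_iterations = 2, num_trees = 60, max_depth = 15),
    segmentation = list(n_segments = 625, merge_threshold = 0.05),
    assessment = list(n_points = 300))
  for (nm in names(defaults))
    cfg[[nm]] <- modifyList(defaults[[nm]], cfg[[nm]] %||% list())
  cfg
}

#' Run the full mapping pipeline on the synthetic demo domain
#'
#' Executes every stage end-to-end and writes the intermediate artifacts
#' (composites, consensus labels, probability map, field polygons,
#' accuracy report) plus a JSON manifest with content hashes under
#' `cfg$out_dir`.
#'
#' @param cfg config list from [load_pipeline_config()] /
#'   [validate_pipeline_config()].
#' @return the manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_pipeline_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  spec <- demo_grid_spec(cfg$grid$pixel_size)

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inst <- stage("fixtures+compositing+learning-setup", function()
    demo_learning_instance(derive_seed(seed, "instance"), spec = spec,
                           n_starter = cfg$learning$n_starter,
                           n_validation = cfg$learning$n_validation,
                           with_labellers = TRUE,
                           crop_fraction = cfg$fixtures$crop_fraction,
                           n_qa = cfg$labelling$n_qa))

  paths <- character(0)
  add <- function(p) { paths <<- c(paths, p); p }

  stage("write-composites", function() {
    for (s in c("growing", "dry")) {
      add(write_raster_tiff(inst$composites[[s]]$values,
                            file.path(out_dir, paste0("composite_", s, ".tif")),
                            inst$geom, bands = BAND_NAMES))
      add(file.path(out_dir, paste0("composite_", s, ".tif.geo.csv")))
    }
    add(write_geojson(inst$landscape$polygons,
                      file.path(out_dir, "truth_fields.geojson")))
  })

  stage("write-labels", function() {
    lab <- inst$labelling
    wdf <- data.frame(labeller_id = names(lab$weights),
                      weight = as.numeric(lab$weights))
    write.csv(wdf, add(file.path(out_dir, "labeller_weights.csv")),
              row.names = FALSE)
    if (!is.null(lab$scores))
      write.csv(lab$scores, add(file.path(out_dir, "qa_scores.csv")),
                row.names = FALSE)
    risk <- data.frame(
      cell_id = names(lab$consensus),
      bayes_risk = vapply(lab$consensus, function(x) x$risk, numeric(1)))
    write.csv(risk, add(file.path(out_dir, "consensus_risk.csv")),
              row.names = FALSE)
  })

  active <- stage("active-learning", function()
    run_active_loop(inst$sites, inst$starter_ids, inst$pool_ids,
                    inst$validation_ids,
                    label_fun = inst$label_funs$consensus,
                    k = cfg$learning$k,
                    max_iterations = cfg$learning$max_iterations,
                    num_trees = cfg$learning$num_trees,
                    max_depth = cfg$learning$max_depth,
                    seed = derive_seed(seed, "active")))
  write.csv(active$log, add(file.path(out_dir, "iteration_log.csv")),
            row.names = FALSE)

  prob <- stage("predict", function()
    predict_probabilities(active$model, inst$features))
  stage("write-prob", function() {
    add(write_raster_tiff(prob, file.path(out_dir, "cropland_prob.tif"),
                          inst$geom, bands = "p"))
    add(file.path(out_dir, "cropland_prob.tif.geo.csv"))
  })

  fields <- stage("segmentation", function() {
    edges <- compute_edge_image(inst$composites$dry, prob)
    segs <- initial_watershed(edges, n_segments = cfg$segmentation$n_segments)
    merged <- merge_regions(segs, inst$composites$dry$values[, , 2:4,
                                                             drop = FALSE],
                            threshold = cfg$segmentation$merge_threshold)
    fs <- filter_by_probability(merged, prob, inst$geom,
                                tile_id = cell_id(inst$tile))
    refine_polygons(fs, tolerance = 0.5, pixel_size = spec$pixel_size)
  })
  stage("write-fields", function() {
    add(write_geojson(fields$polygons,
                      file.path(out_dir, "field_boundaries.geojson"),
                      properties = fields$fields))
    write.csv(fields$fields, add(file.path(out_dir, "fields.csv")),
              row.names = FALSE)
  })

  report <- stage("assessment", function() {
    pred_mask <- (prob > 0.5) * 1L
    truth <- inst$landscape$truth_mask
    set.seed(derive_seed(seed, "refsample"))
    w_crop <- mean(pred_mask)
    n_pts <- cfg$assessment$n_points
    n_crop <- max(10L, round(n_pts * w_crop))
    n_nc <- n_pts - n_crop
    pick <- function(cls, n) {
      idx <- which(pred_mask == cls)
      idx[sample.int(length(idx), min(n, length(idx)))]
    }
    idx <- c(pick(0L, n_nc), pick(1L, n_crop))
    pts <- data.frame(
      map_class = c("non-crop", "crop")[pred_mask[idx] + 1L],
      ref_class = c("non-crop", "crop")[truth[idx] + 1L])
    m <- build_area_matrix(pts, weights = c("non-crop" = 1 - w_crop,
                                            "crop" = w_crop),
                           area_total = domain_area_km2(inst$geom))
    list(matrix = m, accuracy = accuracy_metrics(m), area = estimate_area(m))
  })
  stage("write-assessment", function() {
    acc <- report$accuracy
    df <- data.frame(
      metric = c("overall", "users_crop", "producers_crop"),
      value = c(acc$overall["value"], acc$users["crop", "value"],
                acc$producers[2, "value"]),
      margin = c(acc$overall["margin"], acc$users["crop", "margin"],
                 acc$producers[2, "margin"]))
    write.csv(df, add(file.path(out_dir, "accuracy_report.csv")),
              row.names = FALSE)
    write.csv(report$area, add(file.path(out_dir, "area_estimates.csv")),
              row.names = FALSE)
  })

  manifest <- list(
    seed = seed,
    artifacts = lapply(sort(unique(paths)), function(p)
      list(path = basename(p),
           md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

domain_area_km2 <- function(geom) {
  b <- geom$bounds
  ring <- rbind(c(b["lon0"], b["lat0"]), c(b["lon1"], b["lat0"]),
                c(b["lon1"], b["lat1"]), c(b["lon0"], b["lat1"]))
  abs(geosphere::areaPolygon(ring)) / 1e6
}
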