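# Annotation scoring, labeller quality tracking, task scheduling, and
# Bayesian consensus fusion of four assignments per training cell.

#' Construct an annotation
#'
#' One labeller's complete set of digitized field polygons for one primary
#' grid cell.
#'
#' @param polygons list of `fm_polygon`s.
#' @param labeller_id character.
#' @param cell a primary-level [cell_ref()] or cell id string.
#' @return object of class `annotation`.
#' @export
annotation <- function(polygons, labeller_id, cell) {
  id <- if (inherits(cell, "cell_ref")) cell_id(cell) else cell
  structure(list(polygons = polygons, labeller_id = labeller_id,
                 cell_id = id),
            class = "annotation")
}

#' Rasterize an annotation over its cell window (pixel-center rule)
#'
#' @param ann an `annotation` (or bare list of `fm_polygon`s).
#' @param cell the target primary-level [cell_ref()].
#' @param spec a [grid_spec()].
#' @return ny x nx 0/1 matrix; a pixel is 1 iff its center falls inside any
#'   field polygon.
#' @export
rasterize_annotation <- function(ann, cell, spec) {
  polys <- if (inherits(ann, "annotation")) ann$polygons else ann
  geom <- raster_geom(cell, spec)
  for (p in polys) {
    if (abs(ring_area_signed(p$rings[[1]])) == 0)
      stop("invalid (zero-area) polygon in annotation")
  }
  rasterize_polygons(polys, geom)
}

default_score_weights <- function() {
  c(I = 0.3, O = 0.1, F = 0.2, E = 0.2, C = 0.2)
}

#' Score one assignment against a reference annotation
#'
#' The label quality score is a weighted sum of five components, each in
#' `[0, 1]`:
#' * `I` inside-box accuracy: balanced accuracy (mean of sensitivity and
#'   specificity) of the candidate's rasterized mask against the reference
#'   mask within the cell; a degenerate reference class (no positives or no
#'   negatives) contributes 1 when the candidate matches the degeneracy.
#' * `O` outside accuracy: the fraction of the candidate's area outside the
#'   cell that overlaps reference-outside area; 1 when the candidate does
#'   not extend past the cell.
#' * `F` fragmentation: `min(n_cand, n_ref) / max(n_cand, n_ref)` over
#'   polygon counts; 1 when both are 0.
#' * `E` edge accuracy: candidate and reference polygons are matched by
#'   greatest mask intersection-over-union; `E` is the reference-area
#'   weighted mean IoU of their boundaries dilated by 2 pixels.
#' * `C` categorical accuracy: the fraction of matched candidate polygons
#'   whose thematic class equals the reference class; 1 when nothing is
#'   matched.
#'
#' @param candidate,reference `annotation`s for the same cell.
#' @param cell the target primary-level [cell_ref()].
#' @param spec a [grid_spec()].
#' @param beta weights `(I, O, F, E, C)` summing to 1.
#' @param outside_margin width of the outside evaluation collar, as a
#'   fraction of the cell size.
#' @return object of class `assignment_score` with `components`, `beta` and
#'   `score`.
#' @export
score_assignment <- function(candidate, reference, cell, spec,
                             beta = default_score_weights(),
                             outside_margin = 0.5) {
  if (abs(sum(beta) - 1) > 1e-9) stop("score weights beta must sum to 1")
  if (inherits(candidate, "annotation") && inherits(reference, "annotation") &&
      !identical(candidate$cell_id, reference$cell_id))
    stop("candidate and reference target different cells")
  cand <- if (inherits(candidate, "annotation")) candidate$polygons else candidate
  ref <- if (inherits(reference, "annotation")) reference$polygons else reference
  geom <- raster_geom(cell, spec)

  cmask <- rasterize_polygons(cand, geom)
  rmask <- rasterize_polygons(ref, geom)

  # I: balanced accuracy inside the cell; a degenerate reference class (no
  # positive or no negative pixels) contributes 1 iff the candidate matches
  # that degeneracy, else 0
  pos <- sum(rmask == 1); neg <- sum(rmask == 0)
  sens <- if (pos > 0) sum(cmask == 1 & rmask == 1) / pos else
    as.numeric(!any(cmask == 1))
  spc <- if (neg > 0) sum(cmask == 0 & rmask == 0) / neg else
    as.numeric(!any(cmask == 0))
  I <- (sens + spc) / 2

  # O: outside-the-box accuracy on a collar around the cell
  mgeom <- collar_geom(cell, spec, outside_margin)
  cm <- rasterize_polygons(cand, mgeom)
  rm_ <- rasterize_polygons(ref, mgeom)
  inside <- collar_inside_mask(mgeom, cell)
  c_out <- cm == 1 & !inside
  if (!any(c_out)) O <- 1 else O <- sum(c_out & rm_ == 1) / sum(c_out)

  # F: fragmentation
  n_c <- length(cand); n_r <- length(ref)
  F_ <- if (n_c == 0 && n_r == 0) 1 else
    if (max(n_c, n_r) == 0) 1 else min(n_c, n_r) / max(n_c, n_r)

  # E + C: greedy IoU matching on per-polygon masks over the collar window
  if (n_c == 0 && n_r == 0) {
    E <- 1; C <- 1
  } else if (n_c == 0 || n_r == 0) {
    E <- 0; C <- 1  # nothing to match
  } else {
    cmasks <- lapply(cand, function(p) rasterize_polygons(list(p), mgeom))
    rmasks <- lapply(ref, function(p) rasterize_polygons(list(p), mgeom))
    iou <- matrix(0, n_c, n_r)
    for (i in seq_len(n_c)) for (j in seq_len(n_r)) {
      inter <- sum(cmasks[[i]] & rmasks[[j]])
      if (inter > 0)
        iou[i, j] <- inter / sum(cmasks[[i]] | rmasks[[j]])
    }
    pairs <- greedy_match(iou)
    if (!nrow(pairs)) {
      E <- 0; C <- 1
    } else {
      e_vals <- numeric(nrow(pairs)); wts <- numeric(nrow(pairs))
      cls_ok <- logical(nrow(pairs))
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        cb <- dilate_mask(boundary_mask(cmasks[[i]]), 2L)
        rb <- dilate_mask(boundary_mask(rmasks[[j]]), 2L)
        u <- sum(cb | rb)
        e_vals[k] <- if (u == 0) 1 else sum(cb & rb) / u
        wts[k] <- sum(rmasks[[j]])
        cls_ok[k] <- identical(cand[[i]]$class, ref[[j]]$class)
      }
      if (sum(wts) == 0) wts <- rep(1, length(wts))
      E <- sum(e_vals * wts) / sum(wts)
      C <- mean(cls_ok)
    }
  }

  comps <- c(I = I, O = O, F = F_, E = E, C = C)
  structure(list(components = comps, beta = beta,
                 score = sum(beta * comps)),
            class = "assignment_score")
}

collar_geom <- function(cell, spec, margin) {
  geom <- raster_geom(cell, spec)
  m_px <- ceiling(margin * geom$nx)
  b <- geom$bounds
  list(nx = geom$nx + 2L * m_px, ny = geom$ny + 2L * m_px, px = geom$px,
       bounds = c(lon0 = unname(b["lon0"]) - m_px * geom$px,
                  lat0 = unname(b["lat0"]) - m_px * geom$px,
                  lon1 = unname(b["lon1"]) + m_px * geom$px,
                  lat1 = unname(b["lat1"]) + m_px * geom$px))
}

collar_inside_mask <- function(mgeom, cell) {
  ctr <- pixel_centers(mgeom)
  b <- cell$bounds
  in_lon <- ctr$lon >= b["lon0"] & ctr$lon < b["lon1"]
  in_lat <- ctr$lat >= b["lat0"] & ctr$lat < b["lat1"]
  outer(in_lat, in_lon, "&")
}

boundary_mask <- function(mask) {
  m <- mask == 1
  er <- m
  n_r <- nrow(m); n_c <- ncol(m)
  sh <- function(di, dj) {
    si <- pmin(pmax(seq_len(n_r) + di, 1L), n_r)
    sj <- pmin(pmax(seq_len(n_c) + dj, 1L), n_c)
    m[si, sj]
  }
  interior <- m & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1)
  m & !interior
}

greedy_match <- function(iou) {
  pairs <- matrix(integer(0), 0, 2)
  if (!length(iou)) return(pairs)
  repeat {
    best <- which.max(iou)
    if (iou[best] <= 0) break
    i <- (best - 1) %% nrow(iou) + 1
    j <- (best - 1) %/% nrow(iou) + 1
    pairs <- rbind(pairs, c(i, j))
    iou[i, ] <- -1
    iou[, j] <- -1
  }
  pairs
}

#' Labeller profile and quality weight
#'
#' A labeller's weight in the consensus is the mean of the accuracy
#' assessment scores they accumulated within the AOI; labellers without QA
#' history get the neutral prior 0.5.
#'
#' @param labeller_id character.
#' @return `labeller_profile()`: an empty profile.
#' @export
labeller_profile <- function(labeller_id) {
  structure(list(labeller_id = labeller_id,
                 history = data.frame(aoi = character(0),
                                      score = numeric(0))),
            class = "labeller_profile")
}

#' @rdname labeller_profile
#' @param profile a `labeller_profile`.
#' @param aoi AOI id.
#' @param score an `assignment_score` or bare numeric score.
#' @export
record_score <- function(profile, aoi, score) {
  s <- if (inherits(score, "assignment_score")) score$score else score
  profile$history <- rbind(profile$history,
                           data.frame(aoi = aoi, score = s))
  profile
}

#' @rdname labeller_profile
#' @return `labeller_weight()`: mean AOI score in `[0, 1]`, 0.5 when the
#'   profile has no history for the AOI.
#' @export
labeller_weight <- function(profile, aoi) {
  h <- profile$history[profile$history$aoi == aoi, "score"]
  if (!length(h)) 0.5 else mean(h)
}

#' Fuse assignments into a consensus label
#'
#' Weighted vote per pixel: `p(field) = sum(w_i y_i) / sum(w_i)` with `y_i`
#' each labeller's binary label and `w_i` the labeller's quality weight
#' (the weight sum normalizes the printed posterior so `p` is a
#' probability). Class is `p > 0.5`; the tie `p = 0.5` goes to non-field.
#'
#' @param masks list of equal-shape 0/1 matrices (typically 4).
#' @param weights numeric labeller weights in `[0, 1]`, not all zero.
#' @return object of class `consensus_label`: `p` (posterior matrix),
#'   `class` (0/1 matrix), `risk` (cell-level Bayes risk).
#' @export
merge_consensus <- function(masks, weights) {
  stopifnot(length(masks) >= 1, length(weights) == length(masks))
  if (any(weights < 0) || any(weights > 1)) stop("weights must lie in [0, 1]")
  if (sum(weights) <= 0) stop("labeller weights must not all be zero")
  dm <- dim(masks[[1]])
  p <- matrix(0, dm[1], dm[2])
  for (i in seq_along(masks)) {
    if (!identical(dim(masks[[i]]), dm)) stop("mask shapes differ")
    p <- p + weights[i] * (masks[[i]] == 1)
  }
  p <- p / sum(weights)
  cls <- (p > 0.5) * 1L
  out <- structure(list(p = p, class = cls, risk = NA_real_),
                   class = "consensus_label")
  out$risk <- bayes_risk(out)
  out
}

#' Bayes risk of a consensus label
#'
#' Per pixel, `1 - |2p - 1|`: 0 when the posterior is unanimous (0 or 1), 1
#' at maximal disagreement (p = 0.5). The cell-level risk is the mean over
#' pixels.
#'
#' @param consensus a `consensus_label`, or a bare posterior matrix/vector.
#' @return scalar risk in `[0, 1]`.
#' @export
bayes_risk <- function(consensus) {
  p <- if (inherits(consensus, "consensus_label")) consensus$p else consensus
  mean(1 - abs(2 * p - 1))
}

# --- task queue --------------------------------------------------------------

#' Labelling task queue and scheduler
#'
#' Tasks are typed `training` (4 distinct assignments required before the
#' consensus is built) or `qa` (accuracy assessment, 1 assignment, scored
#' against reference polygons). The scheduler serves each labeller a QA
#' task after every 5 mapped assignments (so every 6th task served is QA),
#' never serves the same training task twice to one labeller, and returns
#' payloads that do not reveal the task type.
#'
#' @param training_ids,qa_ids character vectors of cell ids.
#' @return a `task_queue` object.
#' @export
task_queue <- function(training_ids, qa_ids = character(0)) {
  structure(list(
    tasks = data.frame(
      cell_id = c(training_ids, qa_ids),
      type = rep(c("training", "qa"),
                 c(length(training_ids), length(qa_ids))),
      required = rep(c(4L, 1L), c(length(training_ids), length(qa_ids))),
      done = 0L, stringsAsFactors = FALSE),
    assigned = list(),      # labeller -> character vector of served cell ids
    mapped_since_qa = list()  # labeller -> count
  ), class = "task_queue")
}

#' @rdname task_queue
#' @param queue a `task_queue`.
#' @param labeller_id character.
#' @param qa_rate mapped-to-QA ratio (default 1 QA per 5 mapped).
#' @return `schedule_next()`: list with `task` (list `cell_id`; type hidden)
#'   and the updated `queue`; raises a condition of class
#'   `fieldmapr_queue_exhausted` when nothing can be served.
#' @export
schedule_next <- function(queue, labeller_id, qa_rate = 1 / 5) {
  served <- queue$assigned[[labeller_id]] %||% character(0)
  since <- queue$mapped_since_qa[[labeller_id]] %||% 0L
  per_qa <- round(1 / qa_rate)
  want_qa <- since >= per_qa
  pick <- function(type) {
    open <- queue$tasks$type == type & queue$tasks$done < queue$tasks$required &
      !(queue$tasks$cell_id %in% served)
    which(open)[1]
  }
  i <- if (want_qa) pick("qa") else pick("training")
  if (is.na(i)) i <- if (want_qa) pick("training") else pick("qa")
  if (is.na(i))
    stop(structure(class = c("fieldmapr_queue_exhausted", "error",
                             "condition"),
                   list(message = "task queue exhausted",
                        call = sys.call())))
  task_type <- queue$tasks$type[i]
  queue$tasks$done[i] <- queue$tasks$done[i] + 1L
  queue$assigned[[labeller_id]] <- c(served, queue$tasks$cell_id[i])
  queue$mapped_since_qa[[labeller_id]] <-
    if (task_type == "qa") 0L else since + 1L
  list(task = list(cell_id = queue$tasks$cell_id[i]), queue = queue)
}

#' @rdname task_queue
#' @return `completed_training_tasks()`: cell ids whose 4 assignments are in
#'   (consensus can be built).
#' @export
completed_training_tasks <- function(queue) {
  t <- queue$tasks
  t$cell_id[t$type == "training" & t$done >= t$required]
}
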