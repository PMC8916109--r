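# Stratified map-accuracy assessment and unbiased area estimation from an
# area-proportion error matrix, following the standard good-practices
# stratified estimators, plus the ratio-based field size/count bias
# adjustment.

#' Area-proportion error matrix
#'
#' Cell `p[i, j]` is the estimated areal proportion mapped as class `i`
#' (rows) with reference class `j` (columns): `p_ij = W_i * n_ij / n_i`,
#' where `W_i` is the mapped-area weight of stratum `i` and `n_ij` the
#' sample tallies. Rows are map strata, columns reference classes.
#'
#' @param counts k x k matrix of sample tallies `n_ij` (map class in rows).
#' @param weights length-k mapped-area proportions `W_i` (summing to 1).
#' @param area_total total mapped area (km^2), used by [estimate_area()].
#' @param classes class names.
#' @return object of class `area_error_matrix`.
#' @export
area_error_matrix <- function(counts, weights, area_total = NA,
                              classes = c("non-crop", "crop")) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  stopifnot(ncol(counts) == k, length(weights) == k, all(counts >= 0))
  if (abs(sum(weights) - 1) > 1e-6) stop("strata weights must sum to 1")
  n_i <- rowSums(counts)
  if (any(n_i == 0)) stop("empty stratum in the reference sample")
  p <- counts / n_i * weights
  dimnames(p) <- dimnames(counts) <- list(map = classes, ref = classes)
  structure(list(p = p, counts = counts, weights = weights, n = n_i,
                 area_total = area_total, classes = classes),
            class = "area_error_matrix")
}

#' Build the matrix from labelled reference points
#'
#' @param points data.frame with columns `map_class` (the stratum) and
#'   `ref_class`; extra columns are ignored. Four-level reference labels
#'   (`unsure ...`) collapse to their binary parents; the unsure fraction
#'   is reported as metadata.
#' @param weights named mapped-area proportions per stratum.
#' @param area_total total mapped area (km^2).
#' @param classes class names (strata), default non-crop / crop.
#' @return an `area_error_matrix`; attribute `unsure_fraction` gives the
#'   share of reference labels that were "unsure".
#' @export
build_area_matrix <- function(points, weights, area_total = NA,
                              classes = c("non-crop", "crop")) {
  ref <- as.character(points$ref_class)
  unsure <- grepl("^unsure", ref)
  ref[unsure] <- sub("^unsure(,| but likely)? *", "", ref[unsure])
  map <- as.character(points$map_class)
  if (!all(map %in% classes)) stop("unknown map class among points")
  if (!all(ref %in% classes)) stop("unknown reference class among points")
  counts <- table(factor(map, classes), factor(ref, classes))
  out <- area_error_matrix(unclass(as.matrix(counts)),
                           weights[classes], area_total, classes)
  attr(out, "unsure_fraction") <- mean(unsure)
  out
}

#' Build the matrix from printed cell proportions
#'
#' Reconstructs sample tallies from an already-tabulated proportion matrix
#' (`n_ij = n_i * p_ij / W_i`, with `W_i` the row sum), so worked examples
#' published as area-proportion tables can be re-analyzed.
#'
#' @param p k x k proportion matrix (summing to 1; percentages accepted).
#' @param n length-k per-stratum sample sizes.
#' @param area_total total mapped area (km^2).
#' @param classes class names.
#' @return an `area_error_matrix`.
#' @export
matrix_from_proportions <- function(p, n, area_total = NA,
                                    classes = c("non-crop", "crop")) {
  p <- as.matrix(p)
  if (abs(sum(p) - 100) < 1) p <- p / 100
  if (abs(sum(p) - 1) > 5e-3) stop("proportions must sum to 1 (or 100)")
  p <- p / sum(p)  # absorb print rounding in published tables
  w <- rowSums(p)
  counts <- p / w * n
  out <- area_error_matrix(counts, w, area_total, classes)
  out$n <- n  # keep the stated integer sample sizes
  out
}

#' Accuracy metrics with stratified margins of error
#'
#' Overall accuracy is the diagonal sum of the proportion matrix; user's
#' accuracy of map class i is the row-conditional diagonal
#' (`p_ii / sum_j p_ij`, complement of commission error); producer's
#' accuracy of reference class j is the column-conditional diagonal
#' (complement of omission error). Margins of error are `z` times the
#' stratified standard errors of each estimator.
#'
#' @param m an `area_error_matrix`.
#' @param z normal quantile for the confidence level (1.96 = 95%).
#' @return list with `overall`, `users`, `producers` (each value + margin).
#' @export
accuracy_metrics <- function(m, z = 1.96) {
  p <- m$p; n_i <- m$n; W <- m$weights
  k <- nrow(p)
  overall <- sum(diag(p))
  users <- diag(p) / rowSums(p)
  producers <- diag(p) / colSums(p)
  # variance of overall accuracy
  v_o <- sum(W^2 * users * (1 - users) / pmax(n_i - 1, 1))
  # variance of user's accuracy per map class
  v_u <- users * (1 - users) / pmax(n_i - 1, 1)
  # variance of producer's accuracy (Olofsson-style, proportions as weights)
  nij_ni <- m$counts / rowSums(m$counts)
  v_p <- numeric(k)
  for (j in seq_len(k)) {
    Nhat_j <- sum(W * nij_ni[, j])
    t1 <- W[j]^2 * (1 - producers[j])^2 * users[j] * (1 - users[j]) /
      pmax(n_i[j] - 1, 1)
    t2 <- 0
    for (i in seq_len(k)) {
      if (i == j) next
      t2 <- t2 + W[i]^2 * nij_ni[i, j] * (1 - nij_ni[i, j]) /
        pmax(n_i[i] - 1, 1)
    }
    v_p[j] <- (t1 + producers[j]^2 * t2) / Nhat_j^2
  }
  list(overall = c(value = overall, margin = z * sqrt(v_o)),
       users = cbind(value = users, margin = z * sqrt(v_u)),
       producers = cbind(value = unname(producers),
                         margin = z * sqrt(v_p)))
}

#' Unbiased class-area estimates from the error matrix
#'
#' The adjusted proportion of class k is the reference-column sum
#' `sum_i p_ik`; the stratified standard error is
#' `sqrt(sum_i W_i^2 (n_ik/n_i)(1 - n_ik/n_i)/(n_i - 1))`. Areas are
#' proportions times the total mapped area.
#'
#' @param m an `area_error_matrix` with `area_total` set.
#' @param z normal quantile for the confidence level.
#' @return data.frame per class: `proportion`, `se`, `area`, `margin`
#'   (area units).
#' @export
estimate_area <- function(m, z = 1.96) {
  if (is.na(m$area_total) || m$area_total <= 0)
    stop("area_total must be positive to estimate areas")
  W <- m$weights; n_i <- m$n
  nij_ni <- m$counts / rowSums(m$counts)
  prop <- colSums(m$p)
  se <- vapply(seq_len(ncol(m$p)), function(j)
    sqrt(sum(W^2 * nij_ni[, j] * (1 - nij_ni[, j]) / pmax(n_i - 1, 1))),
    numeric(1))
  data.frame(class = m$classes, proportion = unname(prop), se = se,
             area = unname(prop) * m$area_total,
             margin = z * se * m$area_total, row.names = NULL)
}

#' Field size/count bias adjustment
#'
#' At validation cells both hand-digitized and segmented field statistics
#' exist; their ratio corrects the map-wide segmented statistics:
#' `r_size = mean(digitized size) / mean(segmented size)`, adjusted size =
#' mapped mean size x `r_size`, and analogously for counts.
#'
#' @param map_mean_size,map_count raw map-wide statistics (per AOI).
#' @param digitized_sizes,segmented_sizes per-validation-cell mean field
#'   sizes (or their overall means).
#' @param digitized_counts,segmented_counts per-validation-cell field
#'   counts (or means).
#' @return list with `r_size`, `r_count`, `adjusted_mean_size`,
#'   `adjusted_count`.
#' @export
adjust_field_stats <- function(map_mean_size, map_count,
                               digitized_sizes, segmented_sizes,
                               digitized_counts, segmented_counts) {
  ms <- mean(segmented_sizes); mc <- mean(segmented_counts)
  if (ms <= 0 || mc <= 0) stop("segmented validation means must be positive")
  r_size <- mean(digitized_sizes) / ms
  r_count <- mean(digitized_counts) / mc
  list(r_size = r_size, r_count = r_count,
       adjusted_mean_size = map_mean_size * r_size,
       adjusted_count = map_count * r_count)
}

# --- worked-example error matrices ------------------------------------------

#' Load the bundled published error-matrix table
#'
#' A CSV of area-proportion error matrices for a national cropland map
#' (per-pixel and segmentation-based, countrywide and by zone), shipped in
#' `inst/extdata/reference_error_matrices.csv`. Cell values are areal
#' percentages; `n_noncrop`/`n_crop` are the per-stratum sample sizes and
#' `area_total_km2` the mapped area.
#'
#' @return data.frame of matrix rows.
#' @export
load_reference_matrices <- function() {
  read.csv(system.file("extdata", "reference_error_matrices.csv",
                       package = "fieldmapr"), stringsAsFactors = FALSE)
}

#' Recompute accuracies and adjusted areas for one published matrix
#'
#' @param map `"per_pixel"` or `"segmentation"`.
#' @param zone `"Zone 1"` .. `"Zone 4"` or `"Ghana"`.
#' @param table optional matrix table (default the bundled one).
#' @return list with the `area_error_matrix`, `accuracy` metrics and (when
#'   the area total is present) the `area` estimates.
#' @export
reference_matrix_check <- function(map = "per_pixel", zone = "Ghana",
                                   table = NULL) {
  tab <- table %||% load_reference_matrices()
  row <- tab[tab$map == map & tab$zone == zone, ]
  if (nrow(row) != 1) stop("no such matrix: ", map, " / ", zone)
  p <- rbind(c(row$noncrop_noncrop, row$noncrop_crop),
             c(row$crop_noncrop, row$crop_crop))
  m <- matrix_from_proportions(p, n = c(row$n_noncrop, row$n_crop),
                               area_total = row$area_total_km2)
  acc <- accuracy_metrics(m)
  list(matrix = m, accuracy = acc,
       area = if (!is.na(row$area_total_km2)) estimate_area(m) else NULL)
}

#' Recompute a Table-2-style CSV of error matrices and print a comparison
#'
#' For every matrix row in the file, recomputes overall, user's and
#' producer's accuracies and the adjusted class proportions from the cell
#' proportions, and returns them alongside any stated values in the file.
#'
#' @param path CSV in the bundled layout (see
#'   [load_reference_matrices()]).
#' @return data.frame of recomputed quantities (percent).
#' @export
run_table2_check <- function(path = NULL) {
  tab <- if (is.null(path)) load_reference_matrices() else
    read.csv(path, stringsAsFactors = FALSE)
  need <- c("map", "zone", "noncrop_noncrop", "noncrop_crop",
            "crop_noncrop", "crop_crop", "n_noncrop", "n_crop")
  if (!all(need %in% names(tab))) stop("malformed matrix file")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    chk <- reference_matrix_check(r$map, r$zone, table = tab)
    acc <- chk$accuracy
    data.frame(
      map = r$map, zone = r$zone,
      overall = 100 * acc$overall["value"],
      users_crop = 100 * acc$users["crop", "value"],
      producers_crop = 100 * acc$producers[2, "value"],
      users_noncrop = 100 * acc$users["non-crop", "value"],
      producers_noncrop = 100 * acc$producers[1, "value"],
      adjusted_crop_pct = 100 * sum(chk$matrix$p[, 2]),
      stated_overall = r$stated_overall %||% NA,
      row.names = NULL)
  })
  do.call(rbind, rows)
}
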