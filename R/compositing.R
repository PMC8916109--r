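# Weighted seasonal compositing of daily 4-band reflectance stacks.
#
# Two per-date weights suppress atmospheric contamination: a haze weight
# 1/blue^2 (the blue band brightens under haze and cloud) and a shadow
# weight that switches on 1/NIR^4 for dates whose NIR falls below the
# pixel's seasonal median. The composite is the weight-normalized mean of
# each band over the valid in-season dates.

REFLECTANCE_EPS <- 1e-4

BAND_NAMES <- c("blue", "green", "red", "nir")

#' Season window
#' @param label `"growing"` or `"dry"`.
#' @param start,end `Date`s (start < end).
#' @return object of class `season_window`.
#' @export
season_window <- function(label, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(label %in% c("growing", "dry"), start < end)
  structure(list(label = label, start = start, end = end),
            class = "season_window")
}

#' Per-pixel reflectance time series
#'
#' @param dates vector of `Date`s.
#' @param reflectance n_dates x 4 matrix of (blue, green, red, nir) surface
#'   reflectance in `[0, 1]`.
#' @param valid logical vector of per-date validity (cloud-mask bits when
#'   available; default all valid).
#' @return object of class `pixel_series`.
#' @export
pixel_series <- function(dates, reflectance, valid = NULL) {
  dates <- as.Date(dates)
  reflectance <- matrix(as.numeric(reflectance), nrow = length(dates),
                        dimnames = list(NULL, BAND_NAMES))
  if (any(!is.finite(reflectance)) || any(reflectance < 0))
    stop("reflectance must be finite and >= 0")
  valid <- valid %||% rep(TRUE, length(dates))
  o <- order(dates)
  structure(list(dates = dates[o],
                 reflectance = reflectance[o, , drop = FALSE],
                 valid = valid[o]),
            class = "pixel_series")
}

#' Haze weight of an observation
#'
#' `1 / max(blue, eps)^2`: strictly decreasing in blue-band reflectance, so
#' hazy and clouded (bright-blue) observations are down-weighted.
#'
#' @param blue_t blue-band reflectance(s), `>= 0`.
#' @param eps clamp protecting against division by zero.
#' @return weight(s).
#' @export
haze_weight <- function(blue_t, eps = REFLECTANCE_EPS) {
  if (any(blue_t < 0)) stop("negative reflectance")
  1 / pmax(blue_t, eps)^2
}

#' Shadow weight of an observation
#'
#' As printed in the source formulation: `1 / max(NIR, eps)^4` when NIR is
#' strictly below the median of the pixel's in-season NIR series, else 1.
#' Note this gives *larger* weights to darker observations; the alternative
#' `mode = "dark_downweight"` uses `NIR^4` instead, which down-weights dark
#' (shadowed) observations as the weight's narrative intent describes.
#'
#' @param NIR_t NIR reflectance(s) of the date(s) being weighted.
#' @param NIR_series the pixel's in-season valid NIR values (must be
#'   non-empty); the median uses the midpoint convention for even counts.
#' @param mode `"as_printed"` (default) or `"dark_downweight"`.
#' @param eps division clamp.
#' @return weight(s).
#' @export
shadow_weight <- function(NIR_t, NIR_series,
                          mode = c("as_printed", "dark_downweight"),
                          eps = REFLECTANCE_EPS) {
  mode <- match.arg(mode)
  if (!length(NIR_series)) stop("empty NIR series")
  med <- median(NIR_series)
  below <- NIR_t < med
  w <- rep(1, length(NIR_t))
  if (mode == "as_printed") {
    w[below] <- 1 / pmax(NIR_t[below], eps)^4
  } else {
    w[below] <- pmax(NIR_t[below], eps)^4
  }
  w
}

#' Composite one pixel over a season window
#'
#' Per band, the weighted mean `sum(B_t W1_t W2_t) / sum(W1_t W2_t)` over
#' valid dates inside the window.
#'
#' @param series a [pixel_series()].
#' @param season a [season_window()].
#' @param shadow_mode passed to [shadow_weight()].
#' @return named 4-vector of composited reflectance, or all-`NA` with
#'   attribute `nodata = TRUE` when no valid in-window dates exist; the
#'   attribute `n_dates` records the contributing date count.
#' @export
composite_pixel <- function(series, season,
                            shadow_mode = c("as_printed", "dark_downweight")) {
  shadow_mode <- match.arg(shadow_mode)
  sel <- series$valid & series$dates >= season$start & series$dates <= season$end
  if (!any(sel)) {
    out <- setNames(rep(NA_real_, 4), BAND_NAMES)
    attr(out, "nodata") <- TRUE
    attr(out, "n_dates") <- 0L
    return(out)
  }
  refl <- series$reflectance[sel, , drop = FALSE]
  w1 <- haze_weight(refl[, "blue"])
  w2 <- shadow_weight(refl[, "nir"], refl[, "nir"], mode = shadow_mode)
  w <- w1 * w2
  out <- setNames(as.numeric(colSums(refl * w) / sum(w)), BAND_NAMES)
  attr(out, "nodata") <- FALSE
  attr(out, "n_dates") <- sum(sel)
  out
}

#' Composite a tile stack over a season window
#'
#' Vectorized application of [composite_pixel()] over every pixel of a
#' dated scene stack.
#'
#' @param stack a scene stack: list with `values`, a
#'   `[row, col, band, date]` array (bands ordered blue, green, red, nir),
#'   `dates` (vector of `Date`s) and optional `valid`
#'   (`[row, col, date]` logical array; missing means all valid).
#' @param season a [season_window()].
#' @param shadow_mode passed to [shadow_weight()].
#' @return object of class `seasonal_composite`: list with `values`
#'   (`[row, col, band]` array, `NA` where no valid dates), `season`,
#'   `n_dates` (matrix of contributing-date counts) and `geom` when the
#'   stack carries one.
#' @export
composite_tile <- function(stack, season,
                           shadow_mode = c("as_printed", "dark_downweight")) {
  shadow_mode <- match.arg(shadow_mode)
  v <- stack$values
  if (is.null(v) || length(dim(v)) != 4L) stop("stack$values must be [row, col, band, date]")
  d <- dim(v)
  if (d[3] != 4L) stop("stack must have 4 bands (blue, green, red, nir)")
  if (d[4] != length(stack$dates)) stop("date dimension mismatch")
  dates <- as.Date(stack$dates)
  in_win <- dates >= season$start & dates <= season$end
  if (!any(in_win)) stop("no scenes inside the season window")
  v <- v[, , , in_win, drop = FALSE]
  nd <- sum(in_win)
  valid <- stack$valid
  valid <- if (is.null(valid)) array(TRUE, c(d[1], d[2], nd)) else
    valid[, , in_win, drop = FALSE]

  npix <- d[1] * d[2]
  blue <- matrix(v[, , 1L, ], npix, nd)
  nir <- matrix(v[, , 4L, ], npix, nd)
  vmask <- matrix(valid, npix, nd)

  w1 <- 1 / pmax(blue, REFLECTANCE_EPS)^2
  nir_masked <- nir
  nir_masked[!vmask] <- NA
  med <- apply(nir_masked, 1L, median, na.rm = TRUE)
  below <- nir < med  # recycled column-wise comparison
  below[is.na(below)] <- FALSE  # pixels with no valid dates stay nodata
  w2 <- matrix(1, npix, nd)
  if (shadow_mode == "as_printed") {
    w2[below] <- 1 / pmax(nir[below], REFLECTANCE_EPS)^4
  } else {
    w2[below] <- pmax(nir[below], REFLECTANCE_EPS)^4
  }
  w <- w1 * w2
  w[!vmask] <- 0
  wsum <- rowSums(w)
  out <- array(NA_real_, c(d[1], d[2], 4L))
  for (b in 1:4) {
    bb <- matrix(v[, , b, ], npix, nd)
    num <- rowSums(bb * w)
    vals <- num / wsum
    vals[wsum == 0] <- NA_real_
    out[, , b] <- matrix(vals, d[1], d[2])
  }
  dimnames(out) <- list(NULL, NULL, BAND_NAMES)
  structure(list(values = out, season = season$label,
                 n_dates = matrix(rowSums(vmask), d[1], d[2]),
                 geom = stack$geom %||% NULL),
            class = "seasonal_composite")
}

#' Composite quality grades and score
#'
#' Each seasonal composite is graded 0-3 (3 = best) on four visual-quality
#' categories: residual cloud, cloud shadow, scene-boundary (seam)
#' artifacts, and resolution degradation. The rescaled score is the grade
#' sum over the maximum attainable 12.
#'
#' @param cloud,shadow,seams,resolution integer grades in `{0,1,2,3}`.
#' @return object of class `quality_grade`.
#' @export
quality_grade <- function(cloud, shadow, seams, resolution) {
  g <- c(cloud = cloud, shadow = shadow, seams = seams,
         resolution = resolution)
  if (!all(g %in% 0:3)) stop("grades must be integers in 0..3")
  structure(list(grades = g, score = sum(g) / 12), class = "quality_grade")
}

#' @rdname quality_grade
#' @param grades a `quality_grade`.
#' @return `quality_score()`: the rescaled score in `[0, 1]`.
#' @export
quality_score <- function(grades) {
  stopifnot(inherits(grades, "quality_grade"))
  grades$score
}

#' Write composite quality grades as CSV
#' @param records data.frame with columns `tile_id`, `season` and a
#'   list-column or columns `c1..c4` of grades.
#' @param path output path.
#' @export
write_quality_csv <- function(records, path) {
  stopifnot(all(c("tile_id", "season", "c1", "c2", "c3", "c4") %in%
                  names(records)))
  records$score <- (records$c1 + records$c2 + records$c3 + records$c4) / 12
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
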