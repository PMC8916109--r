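# Shared test fixtures, built in code.

# Demo-scale grid: 0.05-degree tiles, 20 x 20-pixel primary cells.
demo_spec <- demo_grid_spec()

# Production-scale grid (200 x 200-pixel primary cells).
prod_spec <- grid_spec()

# Axis-aligned square polygon from its south-west corner.
sq_poly <- function(lon0, lat0, w, class = "annual cropland") {
  polygon_geom(rbind(c(lon0, lat0), c(lon0 + w, lat0),
                     c(lon0 + w, lat0 + w), c(lon0, lat0 + w)),
               class = class)
}

# Random simple (star-shaped) polygon around a center, for property tests.
random_poly <- function(cx, cy, r_mean, n = 8L) {
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- r_mean * runif(n, 0.5, 1.5)
  polygon_geom(cbind(cx + rad * cos(ang), cy + rad * sin(ang)))
}

# Independent hand-rolled evaluation of the two compositing weights and the
# weighted mean, used as the oracle against composite_pixel().
oracle_composite <- function(bands, valid = rep(TRUE, nrow(bands))) {
  b <- bands[valid, , drop = FALSE]
  w1 <- 1 / pmax(b[, 1], 1e-4)^2
  med <- median(b[, 4])
  w2 <- ifelse(b[, 4] < med, 1 / pmax(b[, 4], 1e-4)^4, 1)
  w <- w1 * w2
  colSums(b * w) / sum(w)
}
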