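# Shared fixtures and independent oracles used across test files.

# small deterministic trap layouts
toy_traps <- function(J = 3, K = 5, spacing = 2) {
  trap_stations(sprintf("T%d", seq_len(J)),
                x = (seq_len(J) - 1) * spacing, y = rep(0, J),
                n_occasions = K, start_date = as.Date("2008-03-01"))
}

grid_traps <- function(nx = 3, ny = 3, spacing = 2, K = 10) {
  g <- expand.grid(x = (seq_len(nx) - 1) * spacing,
                   y = (seq_len(ny) - 1) * spacing)
  trap_stations(sprintf("G%02d", seq_len(nrow(g))), g$x, g$y,
                n_occasions = K, start_date = as.Date("2008-03-01"))
}

# events -> capture array for a hand-specified history matrix y[i, j, k]
array_from_y <- function(y, traps, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("AF%d", seq_len(dim(y)[1]))
  w <- which(y == 1L, arr.ind = TRUE)
  ev <- data.frame(individual_id = ids[w[, 1]],
                   station_id = traps$stations$station_id[w[, 2]],
                   occasion = w[, 3])
  build_capture_array(capture_events(ev), traps)
}

# independent ray-casting point-in-polygon oracle (even-odd rule)
point_in_polygon_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# brute-force Bernoulli log-likelihood oracle: loops every (i, j, k) cell
loglik_oracle <- function(params, latent, arr, C, ss) {
  n <- dim(arr$y)[1]
  M <- length(latent$z)
  act <- arr$traps$active
  ll <- 0
  for (i in seq_len(M)) {
    if (latent$z[i] == 0) {
      if (i <= n && sum(arr$y[i, , ]) > 0) return(-Inf)
      next
    }
    cx <- ss$points$x[latent$centres[i]]
    cy <- ss$points$y[latent$centres[i]]
    for (j in seq_len(dim(arr$y)[2])) {
      d <- sqrt((arr$traps$stations$x[j] - cx)^2 +
                  (arr$traps$stations$y[j] - cy)^2)
      for (k in seq_len(dim(arr$y)[3])) {
        if (act[j, k] == 0L) next
        yy <- if (i <= n) arr$y[i, j, k] else 0L
        cc <- if (i <= n) C[i, j, k] else 0L
        p <- encounter_probability(params, d, cc)
        ll <- ll + stats::dbinom(yy, 1, p, log = TRUE)
      }
    }
  }
  ll
}
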