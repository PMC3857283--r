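# Synthetic-data generators reproducing the canonical paired-station
# camera-trap survey design, so every pipeline stage is testable without
# field data. All generators are pure functions of their inputs and seed.

#' Generating truth for simulation studies
#'
#' Defaults are the canonical study conditions: density 10.73 animals per
#' 100 km^2, baseline encounter rate 0.029, spatial scale 1.69 km,
#' behavioural-response coefficient 1.10, on 13 stations over ~31 km^2
#' surveyed for 63 nightly occasions with a 20 km buffer and 1 km mesh.
#'
#' @param D density per 100 km^2 (ignored when `fixed_N` is given).
#' @param lambda0,sigma,b1 detection parameters, see [secr_params()].
#' @param n_stations,n_occasions survey design.
#' @param buffer_km,spacing_km state-space geometry.
#' @param fixed_N optional fixed population size instead of Poisson(D x
#'   area / 100), for low-variance unit tests.
#' @return A `camsecr_truth` list.
#' @export
simulation_truth <- function(D = 10.73, lambda0 = 0.029, sigma = 1.69,
                             b1 = 1.10, n_stations = 13L,
                             n_occasions = 63L, buffer_km = 20,
                             spacing_km = 1, fixed_N = NULL) {
  stopifnot(D >= 0, lambda0 > 0, sigma > 0, n_stations >= 1,
            n_occasions >= 1, buffer_km > 0, spacing_km > 0)
  structure(list(D = D, lambda0 = lambda0, sigma = sigma, b1 = b1,
                 n_stations = as.integer(n_stations),
                 n_occasions = as.integer(n_occasions),
                 buffer_km = buffer_km, spacing_km = spacing_km,
                 fixed_N = fixed_N),
            class = "camsecr_truth")
}

# area of the convex hull of a point set
.hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Generate a trap array meeting the survey-design rules
#'
#' Stations are laid out on a jittered 45-degree-rotated square lattice (a
#' checkerboard), the densest arrangement that keeps nearest-neighbour
#' spacing above the minimum while leaving no sliding coverage window
#' under-sampled, with the lattice constant scaled so the trap polygon's
#' convex hull approximates `target_area_km2`. Candidate layouts are
#' rejection-sampled until [validate_design()] passes with the given
#' spacing bounds (and, for arrays of 8+ stations, the hull area is within
#' 20% of target). Deterministic given `seed`.
#'
#' @param n_stations number of stations.
#' @param min_spacing_km,max_spacing_km nearest-neighbour bounds (km).
#' @param target_area_km2 target convex-hull area of the array (km^2).
#' @param n_occasions sampling occasions (all stations active throughout).
#' @param start_date survey start `Date`.
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling cap.
#' @return A `camsecr_traps` object.
#' @export
make_trap_array <- function(n_stations = 13L, min_spacing_km = 1.7,
                            max_spacing_km = 3.5, target_area_km2 = 31,
                            n_occasions = 63L,
                            start_date = as.Date("2008-03-01"),
                            seed = NULL, max_attempts = 200L) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_stations)
  stopifnot(n >= 2)
  # compact diamond of checkerboard cells (i + j even), centre outward
  m <- ceiling(sqrt(2 * n)) + 2L
  cells <- expand.grid(i = 0:(2 * m), j = 0:(2 * m))
  cells <- cells[(cells$i + cells$j) %% 2 == 0, , drop = FALSE]
  cx <- mean(range(cells$i)); cy <- mean(range(cells$j))
  rank <- pmax(abs(cells$i - cx), abs(cells$j - cy)) +
    0.1 * (abs(cells$i - cx) + abs(cells$j - cy))
  cells <- cells[order(rank, cells$i, cells$j), , drop = FALSE]
  cells <- cells[seq_len(n), , drop = FALSE]
  check_area <- n >= 8
  a <- min_spacing_km * 1.15  # lattice constant = NN distance, pre-scaling
  for (attempt in seq_len(max_attempts)) {
    h <- a / sqrt(2)
    jit <- min(0.05, (a - min_spacing_km) / 4)
    x <- cells$i * h + stats::runif(n, -jit, jit)
    y <- cells$j * h + stats::runif(n, -jit, jit)
    if (check_area) {  # rescale the lattice toward the target hull area
      area <- .hull_area(x, y)
      scl <- sqrt(target_area_km2 / area)
      a2 <- min(max(a * scl, min_spacing_km * 1.05), max_spacing_km / sqrt(2))
      if (abs(a2 - a) > 1e-3) {
        a <- a2
        next
      }
    }
    tr <- trap_stations(sprintf("S%02d", seq_len(n)), x, y,
                        n_occasions = n_occasions, start_date = start_date)
    rep <- validate_design(tr, min_spacing_km = min_spacing_km,
                           max_spacing_km = max_spacing_km)
    area_ok <- !check_area ||
      abs(.hull_area(x, y) - target_area_km2) <= 0.2 * target_area_km2
    if (rep$pass && area_ok) return(tr)
  }
  stop("could not satisfy the design constraints in ", max_attempts,
       " attempts")
}

#' Simulate a population of activity centres over the state space
#'
#' `N` is Poisson with mean `D/100 * suitable_area` (or fixed), and
#' centres are placed uniformly over the suitable mesh points, covering
#' the full buffered state space so edge effects are present as the SECR
#' estimator assumes.
#'
#' @param ss a `camsecr_statespace`.
#' @param truth a [simulation_truth()].
#' @param seed RNG seed.
#' @return List with `N`, `centres` (indices into `ss$points`), `x`, `y`.
#' @export
simulate_population <- function(ss, truth, seed = NULL) {
  stopifnot(inherits(ss, "camsecr_statespace"),
            inherits(truth, "camsecr_truth"))
  if (!is.null(seed)) set.seed(seed)
  area <- suitable_area(ss)
  if (area <= 0) stop("suitable area must be positive")
  N <- if (!is.null(truth$fixed_N)) {
    as.integer(truth$fixed_N)
  } else {
    stats::rpois(1, truth$D / 100 * area)
  }
  suit <- which(ss$suitable)
  centres <- if (N > 0) suit[sample.int(length(suit), N, replace = TRUE)]
             else integer(0)
  list(N = N, centres = centres,
       x = ss$points$x[centres], y = ss$points$y[centres])
}

#' Simulate capture histories under the behavioural-response model
#'
#' For each animal and trap, occasions are drawn sequentially:
#' `y ~ Bernoulli(p)` with `p` from [encounter_probability()] at the
#' centre-trap distance, switching from the pre- to the post-capture rate
#' after the first capture in that trap (the trap-specific behavioural
#' response). Captured animals receive age/sex-coded ids (all adults, sex
#' 50/50) and a flank photo stream (both flanks photographed with
#' probability `p_both_flanks`, mimicking paired cameras).
#'
#' @param pop population from [simulate_population()].
#' @param traps a `camsecr_traps`.
#' @param truth a [simulation_truth()].
#' @param ss the `camsecr_statespace` the population was simulated on.
#' @param seed RNG seed.
#' @param p_both_flanks probability a capture event yields photos of both
#'   flanks rather than one.
#' @return List with `arr` (capture array of captured individuals),
#'   `events`, `photos`, `n_total` (true N), `captured` (indices into the
#'   population), `centres` (their mesh indices).
#' @export
simulate_capture_histories <- function(pop, traps, truth, ss, seed = NULL,
                                       p_both_flanks = 0.85) {
  stopifnot(inherits(traps, "camsecr_traps"),
            inherits(truth, "camsecr_truth"))
  if (!is.null(seed)) set.seed(seed)
  pars <- secr_params(truth$lambda0, truth$sigma, truth$b1, psi = 0.5)
  J <- nrow(traps$stations)
  K <- traps$n_occasions
  act <- traps$active
  ylist <- list()
  captured <- integer(0)
  for (i in seq_len(pop$N)) {
    d <- sqrt((traps$stations$x - pop$x[i])^2 +
                (traps$stations$y - pop$y[i])^2)
    p0 <- encounter_probability(pars, d, 0)
    p1 <- encounter_probability(pars, d, 1)
    yi <- matrix(0L, J, K)
    for (j in seq_len(J)) {
      caught <- FALSE
      for (k in seq_len(K)) {
        if (act[j, k] == 0L) next
        p <- if (caught) p1[j] else p0[j]
        if (stats::runif(1) < p) {
          yi[j, k] <- 1L
          caught <- TRUE
        }
      }
    }
    if (sum(yi) > 0) {
      captured <- c(captured, i)
      ylist[[length(ylist) + 1]] <- yi
    }
  }
  if (length(captured) == 0) stop("no individuals captured; raise lambda0 ",
                                  "or density")
  sex <- ifelse(stats::runif(length(captured)) < 0.5, "F", "M")
  ids <- sprintf("A%s%02d", sex, seq_along(captured))
  ev <- do.call(rbind, lapply(seq_along(ids), function(m) {
    w <- which(ylist[[m]] == 1L, arr.ind = TRUE)
    data.frame(individual_id = ids[m],
               station_id = traps$stations$station_id[w[, 1]],
               occasion = as.integer(w[, 2]), stringsAsFactors = FALSE)
  }))
  events <- capture_events(ev)
  start <- if (!is.null(traps$start_date)) traps$start_date
           else as.Date("2008-03-01")
  ph <- do.call(rbind, lapply(seq_len(nrow(events)), function(r) {
    both <- stats::runif(1) < p_both_flanks
    flanks <- if (both) c("left", "right")
              else sample(c("left", "right"), 1)
    data.frame(station_id = events$station_id[r],
               timestamp = as.POSIXct(as.character(start), tz = "UTC") +
                 (events$occasion[r] - 1) * 86400 + 20 * 3600 +
                 60 * (seq_along(flanks) - 1),
               species = "leopard", individual_id = events$individual_id[r],
               flank = flanks, stringsAsFactors = FALSE)
  }))
  photos <- photo_records(ph$station_id, ph$timestamp, ph$species,
                          ph$individual_id, ph$flank)
  arr <- build_capture_array(events, traps)
  list(arr = arr, events = events, photos = photos, n_total = pop$N,
       captured = captured, centres = pop$centres[captured])
}

#' Simulate a multi-species photo stream
#'
#' Poisson arrivals per species and station at the given capture
#' frequencies, with optional within-window photo bursts (one animal
#' triggering the camera repeatedly) to exercise the independence filter.
#'
#' @param rates named vector of capture frequencies (independent events per
#'   100 camera days) per species.
#' @param traps a `camsecr_traps`.
#' @param duration_days survey length; defaults to the trap occasions.
#' @param clustering expected number of extra burst photos per event.
#' @param seed RNG seed.
#' @return A `camsecr_photos` data frame.
#' @export
simulate_photo_stream <- function(rates, traps, duration_days = NULL,
                                  clustering = 0, seed = NULL) {
  stopifnot(all(rates >= 0), !is.null(names(rates)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_days)) duration_days <- traps$n_occasions
  start <- if (!is.null(traps$start_date)) traps$start_date
           else as.Date("2008-03-01")
  J <- nrow(traps$stations)
  rows <- list()
  for (sp in names(rates)) {
    n_ev <- stats::rpois(1, rates[[sp]] / 100 * J * duration_days)
    if (n_ev == 0) next
    stn <- traps$stations$station_id[sample.int(J, n_ev, replace = TRUE)]
    day <- sample.int(duration_days, n_ev, replace = TRUE)
    tod <- stats::runif(n_ev, 5 * 3600, 23 * 3600)
    ts <- as.POSIXct(as.character(start), tz = "UTC") +
      (day - 1) * 86400 + tod
    extra <- stats::rpois(n_ev, clustering)
    for (e in seq_len(n_ev)) {
      times <- ts[e] + c(0, cumsum(stats::runif(extra[e], 60, 600)))
      rows[[length(rows) + 1]] <- data.frame(
        station_id = stn[e], timestamp = times, species = sp,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(photo_records(character(0), as.POSIXct(character(0), tz = "UTC"),
                         character(0)))
  }
  df <- do.call(rbind, rows)
  photo_records(df$station_id, df$timestamp, df$species)
}

#' Expand a per-individual capture summary into synthetic events
#'
#' Reconstructs an event table whose per-individual event counts and
#' numbers of capture locations exactly match a printed capture summary
#' (id, total captures, number of capture locations): stations are drawn
#' at random, captures distributed among them (each station at least one),
#' and occasions drawn without replacement within each station. A flank
#' photo stream is attached so deduplication can be exercised end to end.
#'
#' @param summary data frame with `individual_id`, `total_captures`,
#'   `n_capture_locations` (e.g. [leopard_individuals()]).
#' @param traps a `camsecr_traps`.
#' @param seed RNG seed.
#' @param p_both_flanks probability an event yields photos of both flanks.
#' @return List with `events` (a `camsecr_events`) and `photos`.
#' @export
expand_capture_summary <- function(summary, traps, seed = NULL,
                                   p_both_flanks = 0.85) {
  stopifnot(all(c("individual_id", "total_captures",
                  "n_capture_locations") %in% names(summary)))
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(traps$stations)
  K <- traps$n_occasions
  rows <- list()
  for (r in seq_len(nrow(summary))) {
    tot <- summary$total_captures[r]
    L <- summary$n_capture_locations[r]
    stopifnot(L <= J, tot >= L, tot <= L * K)
    stns <- sample.int(J, L)
    alloc <- rep(1L, L)
    if (tot > L) {
      extra <- stats::rmultinom(1, tot - L, rep(1 / L, L))[, 1]
      alloc <- alloc + extra
    }
    while (any(alloc > K)) {  # cannot exceed one event per station-day
      over <- which.max(alloc)
      under <- which.min(alloc)
      alloc[over] <- alloc[over] - 1L
      alloc[under] <- alloc[under] + 1L
    }
    for (l in seq_len(L)) {
      occ <- sort(sample.int(K, alloc[l]))
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = summary$individual_id[r],
        station_id = traps$stations$station_id[stns[l]],
        occasion = occ, stringsAsFactors = FALSE)
    }
  }
  events <- capture_events(do.call(rbind, rows))
  start <- if (!is.null(traps$start_date)) traps$start_date
           else as.Date("2008-03-01")
  ph <- do.call(rbind, lapply(seq_len(nrow(events)), function(r) {
    both <- stats::runif(1) < p_both_flanks
    flanks <- if (both) c("left", "right")
              else sample(c("left", "right"), 1)
    data.frame(station_id = events$station_id[r],
               timestamp = as.POSIXct(as.character(start), tz = "UTC") +
                 (events$occasion[r] - 1) * 86400 + 19 * 3600 +
                 60 * (seq_along(flanks) - 1),
               species = "leopard",
               individual_id = events$individual_id[r],
               flank = flanks, stringsAsFactors = FALSE)
  }))
  photos <- photo_records(ph$station_id, ph$timestamp, ph$species,
                          ph$individual_id, ph$flank)
  list(events = events, photos = photos)
}

#' The canonical synthetic survey bundle
#'
#' A deterministic end-to-end dataset on the canonical design: a 13-station
#' array over ~31 km^2 with 63 occasions; a population simulated at the
#' default [simulation_truth()] over the 20 km-buffered state space;
#' model-based capture histories and flank photos; count-matched events
#' expanded from the packaged individual summary; and a clustered prey
#' photo stream. Regenerating with the same seed reproduces the bundle
#' exactly.
#'
#' @param seed master seed; sub-generators use offsets of it.
#' @param spacing_km mesh spacing for the bundled state space.
#' @return A `camsecr_fixture` list: `traps`, `truth`, `statespace`, `sim`
#'   (model-based simulation), `table1` (individual summary),
#'   `table1_expansion` (count-matched events/photos), `prey_photos`.
#' @export
canonical_fixture <- function(seed = 1403L, spacing_km = 1) {
  seed <- as.integer(seed)
  truth <- simulation_truth(spacing_km = spacing_km)
  traps <- make_trap_array(n_stations = truth$n_stations,
                           n_occasions = truth$n_occasions,
                           seed = seed + 1L)
  ss <- build_statespace(traps, buffer_km = truth$buffer_km,
                         spacing_km = spacing_km)
  pop <- simulate_population(ss, truth, seed = seed + 2L)
  sim <- simulate_capture_histories(pop, traps, truth, ss, seed = seed + 3L)
  table1 <- leopard_individuals()
  exp1 <- expand_capture_summary(table1, traps, seed = seed + 4L)
  prey <- simulate_photo_stream(
    c(bushbuck = 1.56, porcupine = 1.09, baboon = 1.08, kudu = 0.5,
      impala = 0.31, red_duiker = 0.17, common_duiker = 0.12),
    traps, clustering = 1, seed = seed + 5L)
  structure(list(traps = traps, truth = truth, statespace = ss,
                 sim = sim, table1 = table1, table1_expansion = exp1,
                 prey_photos = prey, seed = seed),
            class = "camsecr_fixture")
}

#' Simulate-and-refit parameter-recovery study
#'
#' The pipeline's core self-check: capture histories are simulated on the
#' canonical design at the generating truth, the model is refit at reduced
#' MCMC scale, and the posterior means are compared with the truth.
#' Several independent replicate surveys (seeds derived deterministically
#' from `seed`) are averaged, since with ~10 observed animals a single
#' survey's posterior mean carries sampling noise comparable to its
#' posterior SD.
#'
#' @param seed master seed.
#' @param replicates number of independent simulate-fit replicates.
#' @param truth generating [simulation_truth()]; the default uses a 2 km
#'   mesh for tractable refits.
#' @param iterations,burn_in,augmentation sampler scale per replicate.
#' @return List with `replicates` (per-replicate posterior means, HPD
#'   bounds and design realisations), `estimate` (averaged posterior means
#'   of `D`, `lambda0`, `sigma`, `b1`) and `truth`.
#' @export
recovery_study <- function(seed = 1L, replicates = 5L,
                           truth = simulation_truth(spacing_km = 2),
                           iterations = 25000L, burn_in = 5000L,
                           augmentation = 375L) {
  rows <- list()
  for (r in seq_len(replicates)) {
    base <- as.integer(((as.numeric(seed) * 1000 + r) * 10) %%
                         .Machine$integer.max)
    traps <- make_trap_array(n_stations = truth$n_stations,
                             n_occasions = truth$n_occasions,
                             seed = base + 1L)
    ss <- build_statespace(traps, buffer_km = truth$buffer_km,
                           spacing_km = truth$spacing_km)
    pop <- simulate_population(ss, truth, seed = base + 2L)
    sim <- simulate_capture_histories(pop, traps, truth, ss,
                                      seed = base + 3L)
    fit <- secr_mcmc(sim$arr, ss,
                     config = mcmc_config(iterations = iterations,
                                          burn_in = burn_in,
                                          augmentation = augmentation,
                                          seed = base + 4L))
    s <- suppressWarnings(summarize_posterior(fit))
    g <- function(p, col) s[s$parameter == p, col]
    rows[[r]] <- data.frame(
      replicate = r, n_obs = fit$n_obs, N_true = pop$N,
      D_true = pop$N / fit$suitable_area * 100,
      D = g("D", "mean"), D_sd = g("D", "sd"),
      D_lo = g("D", "hpd_lower"), D_hi = g("D", "hpd_upper"),
      lambda0 = g("lambda0", "mean"), sigma = g("sigma", "mean"),
      sigma_sd = g("sigma", "sd"), b1 = g("b1", "mean"),
      b1_sd = g("b1", "sd"))
  }
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       estimate = c(D = mean(reps$D), lambda0 = mean(reps$lambda0),
                    sigma = mean(reps$sigma), b1 = mean(reps$b1)),
       truth = truth)
}

#' Write a fixture bundle as the three-file CSV dialect
#'
#' Writes `deployment.csv` (station coordinates and per-occasion
#' activity), `captures.csv` (LOC_ID, ANIMAL_ID, SO triplets from the
#' model-based simulation), `statespace.csv` (X, Y, HABITAT),
#' `table1_captures.csv` (count-matched triplets), `leopard_photos.csv`
#' and `prey_photos.csv` (timestamped streams).
#'
#' @param bundle a [canonical_fixture()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "camsecr_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_deployment(bundle$traps, file.path(dir, "deployment.csv"))
  write_captures(bundle$sim$events, file.path(dir, "captures.csv"))
  write_statespace(bundle$statespace, file.path(dir, "statespace.csv"))
  write_captures(bundle$table1_expansion$events,
                 file.path(dir, "table1_captures.csv"))
  write_photos(bundle$sim$photos, file.path(dir, "leopard_photos.csv"))
  write_photos(bundle$prey_photos, file.path(dir, "prey_photos.csv"))
  invisible(dir)
}
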