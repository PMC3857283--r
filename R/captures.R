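# Camera-trap domain objects and capture-array construction.

#' Create a camera-trap station table
#'
#' A station is a paired camera set-up (two cameras facing each other across
#' a trail) and is treated as a single trap: the pairing exists to
#' photograph both flanks of a passing animal, not to double sampling
#' effort. Coordinates are planar (projected, e.g. UTM) in kilometres.
#'
#' @param station_id character vector of unique station labels.
#' @param x,y numeric easting/northing in km.
#' @param n_occasions number of sampling occasions (trap nights).
#' @param active optional J x K binary matrix of per-occasion availability;
#'   defaults to all stations active on all occasions.
#' @param start_date optional `Date` of the first occasion, used to map photo
#'   timestamps to occasions.
#' @return An object of class `camsecr_traps`.
#' @examples
#' tr <- trap_stations(c("S1", "S2"), x = c(0, 2), y = c(0, 0), n_occasions = 5)
#' trap_nights(tr)
#' @export
trap_stations <- function(station_id, x, y, n_occasions, active = NULL,
                          start_date = NULL) {
  station_id <- as.character(station_id)
  if (anyDuplicated(station_id)) {
    stop("duplicate station_id: ",
         paste(unique(station_id[duplicated(station_id)]), collapse = ", "))
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("station coordinates must be finite")
  }
  J <- length(station_id)
  if (length(x) != J || length(y) != J) {
    stop("station_id, x and y must have equal length")
  }
  n_occasions <- as.integer(n_occasions)
  if (is.na(n_occasions) || n_occasions < 1L) stop("n_occasions must be >= 1")
  if (is.null(active)) {
    active <- matrix(1L, J, n_occasions)
  } else {
    active <- matrix(as.integer(active), J, n_occasions)
  }
  if (nrow(active) != J || ncol(active) != n_occasions) {
    stop("active must be a ", J, " x ", n_occasions, " matrix")
  }
  if (!all(active %in% c(0L, 1L))) stop("active entries must be 0 or 1")
  rownames(active) <- station_id
  if (!is.null(start_date)) start_date <- as.Date(start_date)
  structure(list(
    stations = data.frame(station_id = station_id, x = x, y = y,
                          stringsAsFactors = FALSE),
    active = active,
    n_occasions = n_occasions,
    start_date = start_date
  ), class = "camsecr_traps")
}

#' @export
print.camsecr_traps <- function(x, ...) {
  cat("Camera-trap stations:", nrow(x$stations), "stations,",
      x$n_occasions, "occasions,", trap_nights(x), "trap nights\n")
  print(utils::head(x$stations, 5))
  if (nrow(x$stations) > 5) cat("...\n")
  invisible(x)
}

#' Total survey effort in trap nights
#'
#' One trap night is one station active on one occasion; a paired station
#' counts once per night.
#'
#' @param traps a `camsecr_traps` object.
#' @return Integer count of active station-occasions.
#' @export
trap_nights <- function(traps) {
  stopifnot(inherits(traps, "camsecr_traps"))
  as.integer(sum(traps$active))
}

#' Check a trap array against survey-design rules
#'
#' Flags nearest-neighbour spacings outside `[min_spacing_km,
#' max_spacing_km]` and scans an axis-aligned square window of
#' `coverage_area_km2` (stepped at `step_km`) across the trap bounding box,
#' reporting any window position holding fewer than `min_stations` stations.
#' The spacing rule guarantees every resident animal is exposed to capture;
#' the coverage rule guards against holes larger than a small home range.
#'
#' @param traps a `camsecr_traps` object with at least 2 stations.
#' @param min_spacing_km,max_spacing_km allowed nearest-neighbour range (km).
#' @param coverage_area_km2 area of the sliding square window (km^2).
#' @param min_stations minimum stations required inside every window.
#' @param step_km window step (km).
#' @return A `camsecr_design_report` list with elements `nn_distances`,
#'   `spacing_violations` (data frame), `degenerate` (duplicated
#'   coordinates), `coverage_ok`, `min_window_count`, and overall `pass`.
#' @export
validate_design <- function(traps, min_spacing_km = 1.7, max_spacing_km = 3.5,
                            coverage_area_km2 = 9, min_stations = 2,
                            step_km = 0.5) {
  stopifnot(inherits(traps, "camsecr_traps"))
  st <- traps$stations
  if (nrow(st) < 2) stop("validate_design needs at least 2 stations")
  D <- as.matrix(stats::dist(st[, c("x", "y")]))
  degenerate <- character(0)
  if (any(D[upper.tri(D)] == 0)) {
    idx <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
    degenerate <- unique(c(st$station_id[idx[, 1]], st$station_id[idx[, 2]]))
  }
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  names(nn) <- st$station_id
  bad <- nn < min_spacing_km | nn > max_spacing_km
  spacing_violations <- data.frame(
    station_id = st$station_id[bad],
    nearest_neighbour_km = unname(nn[bad]),
    too_close = nn[bad] < min_spacing_km,
    stringsAsFactors = FALSE
  )
  side <- sqrt(coverage_area_km2)
  xs <- seq(min(st$x), max(min(st$x), max(st$x) - side), by = step_km)
  ys <- seq(min(st$y), max(min(st$y), max(st$y) - side), by = step_km)
  counts <- outer(xs, ys, Vectorize(function(x0, y0) {
    sum(st$x >= x0 & st$x <= x0 + side & st$y >= y0 & st$y <= y0 + side)
  }))
  min_window_count <- min(counts)
  report <- list(
    nn_distances = nn,
    spacing_violations = spacing_violations,
    degenerate = degenerate,
    coverage_ok = min_window_count >= min_stations,
    min_window_count = min_window_count,
    window_side_km = side,
    pass = nrow(spacing_violations) == 0 && min_window_count >= min_stations &&
      length(degenerate) == 0
  )
  class(report) <- "camsecr_design_report"
  report
}

#' @export
print.camsecr_design_report <- function(x, ...) {
  cat("Survey design check:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  nearest-neighbour range:",
      sprintf("%.2f-%.2f km", min(x$nn_distances), max(x$nn_distances)), "\n")
  if (nrow(x$spacing_violations)) {
    cat("  spacing violations:\n")
    print(x$spacing_violations)
  }
  if (length(x$degenerate)) {
    cat("  degenerate (duplicated) coordinates:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  cat("  coverage: min stations per", sprintf("%.1f km window:", x$window_side_km),
      x$min_window_count, if (x$coverage_ok) "(ok)" else "(below minimum)", "\n")
  invisible(x)
}

# ---- individuals -----------------------------------------------------------

#' Parse age/sex coded individual identifiers
#'
#' Identifiers follow the field convention `AF`/`AM`/`JF`/`JM` + number
#' (adult/juvenile crossed with female/male), e.g. `"AF1"`, `"JM2"`.
#'
#' @param id character vector of identifiers.
#' @return Data frame with `individual_id`, `age_class`
#'   (`"adult"`/`"juvenile"`) and `sex` (`"female"`/`"male"`); unparseable
#'   ids get `NA` with a warning.
#' @export
parse_individual_id <- function(id) {
  id <- as.character(id)
  m <- regexec("^([AJ])([FM])[0-9]+$", id)
  parts <- regmatches(id, m)
  ok <- lengths(parts) == 3L
  if (any(!ok)) {
    warning("unparseable individual id(s): ",
            paste(unique(id[!ok]), collapse = ", "))
  }
  age <- ifelse(ok, ifelse(vapply(parts, function(p) p[2], "",
                                  USE.NAMES = FALSE) == "A",
                           "adult", "juvenile"), NA_character_)
  sex <- ifelse(ok, ifelse(vapply(parts, function(p) p[3], "",
                                  USE.NAMES = FALSE) == "F",
                           "female", "male"), NA_character_)
  data.frame(individual_id = id, age_class = age, sex = sex,
             stringsAsFactors = FALSE)
}

#' Load the packaged individual capture summary
#'
#' A small CSV shipped with the package listing the individuals identified
#' in the canonical leopard survey (id, age class, sex, total captures,
#' number of capture locations). Used as a fixture for counting and
#' classification operations and as the per-individual capture-count target
#' for count-matched synthetic events.
#'
#' @return Data frame with columns `individual_id`, `age_class`, `sex`,
#'   `total_captures`, `n_capture_locations`.
#' @export
leopard_individuals <- function() {
  path <- system.file("extdata", "leopard_individuals.csv",
                      package = "camsecr", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parsed <- parse_individual_id(df$individual_id)
  stopifnot(identical(parsed$age_class, df$age_class),
            identical(parsed$sex, df$sex))
  df
}

# ---- reading records -------------------------------------------------------

#' Read an animal-capture file
#'
#' Accepts two dialects. The three-column survey dialect `LOC_ID,
#' ANIMAL_ID, SO` (station, individual, sampling occasion) is returned
#' directly as capture events. The timestamped dialect `station, datetime,
#' species[, individual, flank]` is returned as photographic records for
#' [dedupe_photos()] / [independent_events()].
#'
#' @param path CSV file path.
#' @param traps optional `camsecr_traps`; if given, station ids are checked
#'   against the deployment and unknown ids raise an error naming them.
#' @return A `camsecr_events` data frame (`individual_id`, `station_id`,
#'   `occasion`) or a `camsecr_photos` data frame (`station_id`, `timestamp`,
#'   `species`, `individual_id`, `flank`).
#' @export
read_captures <- function(path, traps = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- toupper(names(df))
  if (all(c("LOC_ID", "ANIMAL_ID", "SO") %in% nm)) {
    names(df) <- nm
    occ <- suppressWarnings(as.integer(df$SO))
    bad <- which(is.na(df$LOC_ID) | df$LOC_ID == "" |
                   is.na(df$ANIMAL_ID) | df$ANIMAL_ID == "" | is.na(occ))
    if (length(bad)) {
      stop("unparseable capture rows at line(s): ",
           paste(bad + 1L, collapse = ", "))
    }
    out <- data.frame(individual_id = as.character(df$ANIMAL_ID),
                      station_id = as.character(df$LOC_ID),
                      occasion = occ, stringsAsFactors = FALSE)
    .check_stations(out$station_id, traps)
    return(capture_events(out))
  }
  lnm <- tolower(names(df))
  if (all(c("station", "datetime", "species") %in% lnm)) {
    names(df) <- lnm
    ts <- as.POSIXct(df$datetime, tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
    bad <- which(is.na(ts) | is.na(df$station) | df$station == "")
    if (length(bad)) {
      stop("unparseable photo rows at line(s): ",
           paste(bad + 1L, collapse = ", "))
    }
    .check_stations(df$station, traps)
    return(photo_records(
      station_id = df$station, timestamp = ts, species = df$species,
      individual_id = if ("individual" %in% lnm) df$individual else NA,
      flank = if ("flank" %in% lnm) df$flank else "unknown"
    ))
  }
  stop("format error: expected columns LOC_ID,ANIMAL_ID,SO or ",
       "station,datetime,species[,individual,flank]; found: ",
       paste(names(df), collapse = ", "))
}

.check_stations <- function(ids, traps) {
  if (is.null(traps)) return(invisible(TRUE))
  unknown <- setdiff(unique(ids), traps$stations$station_id)
  if (length(unknown)) {
    stop("station id(s) absent from deployment: ",
         paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a photographic record table
#'
#' @param station_id station labels.
#' @param timestamp `POSIXct` timestamps (minute resolution is sufficient).
#' @param species species labels.
#' @param individual_id individual ids for marked animals, `NA` otherwise.
#' @param flank `"left"`, `"right"` or `"unknown"`.
#' @return A `camsecr_photos` data frame sorted by station and time.
#' @export
photo_records <- function(station_id, timestamp, species,
                          individual_id = NA, flank = "unknown") {
  n <- max(length(station_id), length(timestamp), length(species))
  df <- data.frame(station_id = rep_len(as.character(station_id), n),
                   timestamp = rep_len(as.POSIXct(timestamp, tz = "UTC"), n),
                   species = rep_len(as.character(species), n),
                   individual_id = rep_len(as.character(individual_id), n),
                   flank = rep_len(as.character(flank), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$station_id, df$timestamp, df$species), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("camsecr_photos", "data.frame")
  df
}

#' Construct a capture-event table
#'
#' @param df data frame with `individual_id`, `station_id`, `occasion`.
#' @return A `camsecr_events` data frame, deterministically ordered.
#' @export
capture_events <- function(df) {
  stopifnot(all(c("individual_id", "station_id", "occasion") %in% names(df)))
  df <- df[, c("individual_id", "station_id", "occasion")]
  df$individual_id <- as.character(df$individual_id)
  df$station_id <- as.character(df$station_id)
  df$occasion <- as.integer(df$occasion)
  df <- unique(df)
  df <- df[order(df$individual_id, df$station_id, df$occasion), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("camsecr_events", "data.frame")
  df
}

#' Collapse flank photographs into capture events
#'
#' Paired stations photograph both flanks of a passing animal, so the photo
#' count exceeds the event count. All photos of one individual at one
#' station within one occasion (calendar day) collapse to a single capture
#' event, matching the one-capture-per-trap-per-night observation model.
#'
#' @param photos a `camsecr_photos` data frame of marked-individual photos;
#'   every row must carry an `individual_id`.
#' @param start_date survey start `Date`; defaults to the earliest photo day.
#' @return A `camsecr_events` data frame with 1-based day occasions.
#' @export
dedupe_photos <- function(photos, start_date = NULL) {
  stopifnot(is.data.frame(photos))
  if (nrow(photos) == 0) {
    return(capture_events(data.frame(individual_id = character(0),
                                     station_id = character(0),
                                     occasion = integer(0))))
  }
  if (any(is.na(photos$individual_id) | photos$individual_id == "")) {
    stop("photos without individual_id cannot be deduplicated into ",
         "marked-individual capture events")
  }
  day <- as.Date(photos$timestamp, tz = "UTC")
  if (is.null(start_date)) start_date <- min(day)
  occ <- as.integer(day - as.Date(start_date)) + 1L
  if (any(occ < 1L)) stop("photo timestamp before survey start")
  capture_events(data.frame(individual_id = photos$individual_id,
                            station_id = photos$station_id,
                            occasion = occ, stringsAsFactors = FALSE))
}

# ---- capture array ---------------------------------------------------------

#' Build the binary capture array
#'
#' Assembles deduplicated events into the individuals x traps x occasions
#' binary array `y` used by the SECR likelihood. Individuals are ordered
#' lexicographically by id so runs are reproducible; traps keep deployment
#' order. With `adults_only = TRUE` juveniles are dropped before the array
#' is built (standard practice: cubs have low capture probability and
#' sub-adults may be transient, so densities are computed for adults).
#'
#' @param events a `camsecr_events` data frame.
#' @param traps a `camsecr_traps` object.
#' @param individuals optional data frame with `individual_id`, `age_class`,
#'   `sex`; parsed from the id convention when omitted.
#' @param adults_only drop juveniles before building.
#' @return A `camsecr_capture_array` with elements `y` (3-d array),
#'   `individuals`, `traps`, `n_occasions`.
#' @export
build_capture_array <- function(events, traps, individuals = NULL,
                                adults_only = FALSE) {
  stopifnot(inherits(traps, "camsecr_traps"))
  events <- capture_events(events)
  if (is.null(individuals)) {
    individuals <- parse_individual_id(unique(events$individual_id))
  }
  individuals <- individuals[order(individuals$individual_id), , drop = FALSE]
  rownames(individuals) <- NULL
  if (adults_only) {
    individuals <- individuals[!is.na(individuals$age_class) &
                                 individuals$age_class == "adult", ,
                               drop = FALSE]
  }
  events <- events[events$individual_id %in% individuals$individual_id, ,
                   drop = FALSE]
  if (nrow(individuals) == 0 || nrow(events) == 0) {
    stop("no individuals with capture events",
         if (adults_only) " (after removing juveniles)" else "")
  }
  .check_stations(events$station_id, traps)
  K <- traps$n_occasions
  if (any(events$occasion < 1L | events$occasion > K)) {
    stop("event occasion outside 1..", K)
  }
  jidx <- match(events$station_id, traps$stations$station_id)
  inact <- traps$active[cbind(jidx, events$occasion)] == 0L
  if (any(inact)) {
    off <- events[inact, , drop = FALSE]
    stop("events recorded at inactive traps: ",
         paste(sprintf("%s@%s/occ%d", off$individual_id, off$station_id,
                       off$occasion), collapse = "; "))
  }
  ids <- individuals$individual_id
  y <- array(0L, dim = c(length(ids), nrow(traps$stations), K),
             dimnames = list(ids, traps$stations$station_id, NULL))
  y[cbind(match(events$individual_id, ids), jidx, events$occasion)] <- 1L
  structure(list(y = y, individuals = individuals, traps = traps,
                 n_occasions = K),
            class = "camsecr_capture_array")
}

#' @export
print.camsecr_capture_array <- function(x, ...) {
  d <- dim(x$y)
  cat("Capture array:", d[1], "individuals x", d[2], "traps x", d[3],
      "occasions;", sum(x$y), "captures\n")
  invisible(x)
}

#' Prior-capture indicator for the behavioural response
#'
#' `C[i, j, k] = 1` iff individual `i` was captured in trap `j` on some
#' occasion before `k`. Under the trap-specific behavioural response the
#' encounter rate in a trap changes after the first capture in that trap;
#' `C` is the covariate carrying that switch.
#'
#' @param arr a `camsecr_capture_array`.
#' @return Binary array with the same dimensions as `arr$y`, zero on the
#'   first occasion and non-decreasing along occasions.
#' @export
prior_capture_indicator <- function(arr) {
  stopifnot(inherits(arr, "camsecr_capture_array"))
  y <- arr$y
  d <- dim(y)
  C <- array(0L, dim = d, dimnames = dimnames(y))
  if (d[3] > 1) {
    cum <- y
    for (k in 2:d[3]) cum[, , k] <- pmax(cum[, , k - 1], y[, , k])
    C[, , 2:d[3]] <- cum[, , 1:(d[3] - 1), drop = FALSE]
  }
  C
}

# Sufficient statistics for the two-state (pre/post first capture)
# Bernoulli likelihood: per individual x trap, the number of active
# occasions and captures before/at first capture (state 0) and after it
# (state 1). Inactive occasions carry no information and are excluded.
capture_suffstats <- function(arr) {
  y <- arr$y
  n <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  act <- arr$traps$active
  y0 <- y1 <- K0 <- K1 <- matrix(0L, n, J)
  for (i in seq_len(n)) {
    for (j in seq_len(J)) {
      a <- which(act[j, ] == 1L)
      yy <- y[i, j, a]
      first <- if (any(yy == 1L)) which(yy == 1L)[1] else length(a)
      K0[i, j] <- first
      K1[i, j] <- length(a) - first
      y0[i, j] <- as.integer(any(yy == 1L))
      y1[i, j] <- sum(yy) - y0[i, j]
    }
  }
  list(y0 = y0, y1 = y1, K0 = K0, K1 = K1,
       trap_nights_per_trap = rowSums(act))
}
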