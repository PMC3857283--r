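# Relative abundance indices for unmarked (prey) species from photo streams.

#' Filter a photo stream to independent events
#'
#' Within each station the stream is scanned in time order: the first photo
#' of a species is independent; a later photo of the same species is
#' independent iff it falls more than `window_hours` after the comparison
#' photo, or a photo of a different species intervened. By default the
#' comparison is against the immediately preceding photo at that station
#' (`compare = "previous_photo"`); `compare = "previous_event"` instead
#' compares against the species' last *independent* event there.
#' Filtering is per station: independence models one animal lingering in
#' front of one camera.
#'
#' @param photos a `camsecr_photos` data frame.
#' @param window_hours independence window (hours).
#' @param compare comparison convention, see above.
#' @return The independent subset of `photos`, sorted by station and time.
#' @export
independent_events <- function(photos, window_hours = 1,
                               compare = c("previous_photo",
                                           "previous_event")) {
  compare <- match.arg(compare)
  stopifnot(is.data.frame(photos), window_hours > 0)
  if (nrow(photos) == 0) return(photos)
  photos <- photos[order(photos$station_id, photos$timestamp), , drop = FALSE]
  keep <- logical(nrow(photos))
  win <- window_hours * 3600
  for (stn in unique(photos$station_id)) {
    idx <- which(photos$station_id == stn)
    last_species <- NA_character_
    last_time <- list()  # per-species time of the comparison photo/event
    for (r in idx) {
      sp <- photos$species[r]
      tm <- as.numeric(photos$timestamp[r])
      indep <- if (!sp %in% names(last_time)) {
        TRUE
      } else if (!is.na(last_species) && last_species != sp) {
        TRUE  # a different species intervened
      } else {
        tm - last_time[[sp]] > win
      }
      keep[r] <- indep
      if (compare == "previous_photo" || indep) last_time[[sp]] <- tm
      last_species <- sp
    }
  }
  out <- photos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Capture frequency per 100 camera days
#'
#' @param events an event table (or data frame) whose rows are independent
#'   photos, or a single event count.
#' @param camera_days total survey effort in station-nights (> 0), e.g.
#'   [trap_nights()].
#' @return `100 * n_events / camera_days`.
#' @export
capture_frequency <- function(events, camera_days) {
  if (!(is.numeric(camera_days) && camera_days > 0)) {
    stop("camera_days must be positive")
  }
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  100 * n / camera_days
}

#' Days of effort to first photograph (relative abundance index)
#'
#' The RAI is the number of whole days of survey effort before a species
#' was first photographed: 0 means detected on the day the survey began
#' (low effort, suggesting high local density); larger values mean more
#' effort and suggest lower density.
#'
#' @param photos a `camsecr_photos` data frame (all stations pooled).
#' @param species species label.
#' @param survey_start survey start `Date` (must not postdate any photo).
#' @return Integer day count; `NA` with a warning when the species was
#'   never photographed ("not detected").
#' @export
rai_score <- function(photos, species, survey_start) {
  survey_start <- as.Date(survey_start)
  hit <- photos[photos$species == species, , drop = FALSE]
  if (nrow(hit) == 0) {
    warning("species not detected: ", species)
    return(NA_integer_)
  }
  days <- as.Date(hit$timestamp, tz = "UTC")
  if (any(days < survey_start)) stop("photo predates survey_start")
  as.integer(min(days) - survey_start)
}

#' Relative-abundance table for a photo stream
#'
#' One row per species with its independent-event count, capture frequency
#' per 100 camera days and RAI, sorted by capture frequency descending.
#'
#' @param photos a `camsecr_photos` data frame.
#' @param camera_days total effort in station-nights.
#' @param survey_start survey start `Date`; defaults to the earliest photo
#'   day.
#' @param window_hours independence window passed to
#'   [independent_events()].
#' @param exclude species to drop (e.g. the marked focal species when
#'   tabulating prey).
#' @return Data frame with `species`, `n_events`, `capture_frequency`,
#'   `rai`, `detected`.
#' @export
rai_table <- function(photos, camera_days, survey_start = NULL,
                      window_hours = 1, exclude = character(0)) {
  stopifnot(is.data.frame(photos))
  photos <- photos[!photos$species %in% exclude, , drop = FALSE]
  if (nrow(photos) == 0) {
    return(data.frame(species = character(0), n_events = integer(0),
                      capture_frequency = numeric(0), rai = integer(0),
                      detected = logical(0)))
  }
  if (is.null(survey_start)) {
    survey_start <- min(as.Date(photos$timestamp, tz = "UTC"))
  }
  ev <- independent_events(photos, window_hours = window_hours)
  species <- sort(unique(photos$species))
  rows <- lapply(species, function(sp) {
    n <- sum(ev$species == sp)
    data.frame(species = sp, n_events = n,
               capture_frequency = capture_frequency(n, camera_days),
               rai = suppressWarnings(rai_score(photos, sp, survey_start)),
               detected = n > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$capture_frequency, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
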