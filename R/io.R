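# Delimited-text I/O for the three-file survey dialect.

#' Read / write a trap-deployment file
#'
#' Format: `LOC_ID, X, Y`, then one 0/1 column per occasion giving each
#' station's availability that night. Coordinates are km; files in metres
#' (values exceeding 10,000) are converted on read.
#'
#' @param path CSV file path.
#' @param start_date optional survey start `Date` attached to the result.
#' @return `read_deployment` returns a `camsecr_traps`;
#'   `write_deployment` returns `path` invisibly.
#' @export
read_deployment <- function(path, start_date = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- toupper(names(df))
  if (!all(c("LOC_ID", "X", "Y") %in% nm)) {
    stop("format error: deployment file needs columns LOC_ID, X, Y plus ",
         "one column per occasion")
  }
  names(df) <- ifelse(nm %in% c("LOC_ID", "X", "Y"), nm, names(df))
  occ_cols <- setdiff(names(df), c("LOC_ID", "X", "Y"))
  if (length(occ_cols) == 0) stop("deployment file has no occasion columns")
  active <- as.matrix(df[, occ_cols, drop = FALSE])
  x <- as.numeric(df$X); y <- as.numeric(df$Y)
  if (max(abs(c(x, y))) > 1e4) {  # metres -> km
    x <- x * 1e-3; y <- y * 1e-3
  }
  trap_stations(df$LOC_ID, x, y, n_occasions = length(occ_cols),
                active = active, start_date = start_date)
}

#' @rdname read_deployment
#' @param traps a `camsecr_traps` object.
#' @export
write_deployment <- function(traps, path) {
  stopifnot(inherits(traps, "camsecr_traps"))
  act <- as.data.frame(traps$active)
  names(act) <- sprintf("O%d", seq_len(traps$n_occasions))
  df <- cbind(data.frame(LOC_ID = traps$stations$station_id,
                         X = traps$stations$x, Y = traps$stations$y),
              act)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write capture events / photo records
#'
#' `write_captures` emits the `LOC_ID, ANIMAL_ID, SO` triplet dialect;
#' `write_photos` emits the timestamped `station, datetime, species,
#' individual, flank` dialect. Both round-trip through [read_captures()].
#'
#' @param events a `camsecr_events` data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(events, path) {
  df <- data.frame(LOC_ID = events$station_id,
                   ANIMAL_ID = events$individual_id,
                   SO = events$occasion)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_captures
#' @param photos a `camsecr_photos` data frame.
#' @export
write_photos <- function(photos, path) {
  df <- data.frame(station = photos$station_id,
                   datetime = format(photos$timestamp, "%Y-%m-%d %H:%M:%S",
                                     tz = "UTC"),
                   species = photos$species,
                   individual = photos$individual_id,
                   flank = photos$flank)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
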