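# State-space (activity-centre mesh) construction and habitat masking.

#' Build the discretised state space of candidate activity centres
#'
#' The state space S is a regular mesh covering the rectangle that encloses
#' the trap array plus a buffer on every side. The buffer must be wide
#' enough that no animal centred outside S has any appreciable probability
#' of being photographed; the mesh approximates the continuous point
#' process of activity centres. The grid is anchored at
#' `(xmin - buffer, ymin - buffer)` with inclusive endpoints, so the point
#' count is `(floor(span_x/spacing) + 1) * (floor(span_y/spacing) + 1)`.
#'
#' @param traps a `camsecr_traps` object.
#' @param buffer_km buffer width in km (> 0); 20 km is the canonical choice.
#' @param spacing_km mesh spacing in km (> 0); 1 km is the canonical choice,
#'   coarser meshes are useful for fast tests.
#' @return A `camsecr_statespace`: `points` (data frame of x, y in km),
#'   `suitable` logical flags (all `TRUE` initially), `spacing`, `buffer`,
#'   grid dimensions `nx`, `ny` and origin `x0`, `y0`.
#' @examples
#' tr <- trap_stations(c("A", "B"), x = c(0, 6), y = c(0, 5), n_occasions = 10)
#' ss <- build_statespace(tr, buffer_km = 10, spacing_km = 1)
#' nrow(ss$points)  # 27 * 26 = 702
#' @export
build_statespace <- function(traps, buffer_km = 20, spacing_km = 1) {
  stopifnot(inherits(traps, "camsecr_traps"))
  if (!(buffer_km > 0)) stop("buffer_km must be > 0")
  if (!(spacing_km > 0)) stop("spacing_km must be > 0")
  if (spacing_km > 2 * buffer_km) {
    warning("mesh spacing ", spacing_km,
            " km is coarse relative to buffer ", buffer_km, " km")
  }
  xr <- range(traps$stations$x)
  yr <- range(traps$stations$y)
  xs <- seq(xr[1] - buffer_km, xr[2] + buffer_km + 1e-9, by = spacing_km)
  ys <- seq(yr[1] - buffer_km, yr[2] + buffer_km + 1e-9, by = spacing_km)
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  structure(list(
    points = pts,
    suitable = rep(TRUE, nrow(pts)),
    spacing = spacing_km,
    buffer = buffer_km,
    nx = length(xs), ny = length(ys),
    x0 = xs[1], y0 = ys[1]
  ), class = "camsecr_statespace")
}

#' Area of suitable habitat in the state space
#'
#' Each mesh point represents a `spacing^2` km^2 cell, so the suitable area
#' is the number of suitable points times the cell area.
#'
#' @param ss a `camsecr_statespace`.
#' @return Area in km^2.
#' @export
suitable_area <- function(ss) {
  stopifnot(inherits(ss, "camsecr_statespace"))
  sum(ss$suitable) * ss$spacing^2
}

#' @export
print.camsecr_statespace <- function(x, ...) {
  cat("State space:", nrow(x$points), "mesh points at", x$spacing,
      "km spacing", if (!is.na(x$buffer)) paste0("(buffer ", x$buffer, " km)"),
      "\n  suitable:", sum(x$suitable), "points =", suitable_area(x), "km^2\n")
  invisible(x)
}

#' Define a habitat mask from circular exclusions
#'
#' A convenience mask generator for unsuitable habitat patches (e.g. arable
#' fields offering no hunting cover), represented as circles in the same
#' planar km coordinates as the state space.
#'
#' @param centres two-column matrix (x, y) of circle centres, km.
#' @param radius_km radius (recycled over centres), km.
#' @return A `camsecr_mask` object.
#' @export
mask_circles <- function(centres, radius_km) {
  centres <- matrix(as.numeric(centres), ncol = 2)
  radius_km <- rep_len(as.numeric(radius_km), nrow(centres))
  stopifnot(all(radius_km > 0), all(is.finite(centres)))
  structure(list(type = "circles", centres = centres, radius = radius_km),
            class = "camsecr_mask")
}

#' Define a habitat mask from polygons
#'
#' @param polygons a list of two-column (x, y) matrices, each one polygon
#'   ring in planar km coordinates (closing edge implicit).
#' @return A `camsecr_mask` object.
#' @export
mask_polygons <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  stopifnot(all(vapply(polygons, function(p) is.matrix(p) && ncol(p) == 2,
                       TRUE)))
  structure(list(type = "polygons", polygons = polygons),
            class = "camsecr_mask")
}

#' Remove unsuitable habitat from the state space
#'
#' Flags mesh points falling inside the mask as unsuitable, reducing the
#' suitable area accordingly. Only candidate activity centres are masked;
#' trap positions are never removed. Masking composes: points already
#' unsuitable stay unsuitable.
#'
#' @param ss a `camsecr_statespace`.
#' @param mask a `camsecr_mask` (circles or polygons), a logical vector of
#'   length `nrow(ss$points)` flagging points to remove, or a function of
#'   the state space returning such a vector (useful when the same mask
#'   rule must be applied across different buffers); `NULL` or an empty
#'   mask leaves `ss` unchanged.
#' @return The masked `camsecr_statespace`.
#' @export
apply_habitat_mask <- function(ss, mask) {
  stopifnot(inherits(ss, "camsecr_statespace"))
  if (is.null(mask)) return(ss)
  if (is.function(mask)) mask <- mask(ss)
  if (is.logical(mask)) {
    if (length(mask) != nrow(ss$points)) {
      stop("logical mask must have one flag per mesh point")
    }
    inside <- mask
  } else if (inherits(mask, "camsecr_mask")) {
    inside <- rep(FALSE, nrow(ss$points))
    if (mask$type == "circles") {
      for (i in seq_len(nrow(mask$centres))) {
        d2 <- (ss$points$x - mask$centres[i, 1])^2 +
          (ss$points$y - mask$centres[i, 2])^2
        inside <- inside | d2 <= mask$radius[i]^2
      }
    } else {
      for (poly in mask$polygons) {
        inside <- inside | mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                                        as.matrix(ss$points))
      }
    }
  } else {
    stop("mask must be NULL, a logical vector, a function or a camsecr_mask")
  }
  ss$suitable <- ss$suitable & !inside
  if (!any(ss$suitable)) stop("mask removes all habitat: no suitable points")
  ss
}

#' Write / read a state-space file
#'
#' The file format is the three-column CSV `X, Y, HABITAT` used by
#' SPACECAP-style SECR software: coordinates of potential home-range
#' centres and a 0/1 habitat-suitability flag. Coordinates are written in
#' km; files in metres (coordinates exceeding 10,000 in absolute value) are
#' converted on read.
#'
#' @param ss a `camsecr_statespace`.
#' @param path CSV file path.
#' @return `write_statespace` returns `path` invisibly; `read_statespace`
#'   returns a `camsecr_statespace` (with `buffer = NA`, unrecoverable from
#'   the file alone).
#' @export
write_statespace <- function(ss, path) {
  stopifnot(inherits(ss, "camsecr_statespace"))
  df <- data.frame(X = ss$points$x, Y = ss$points$y,
                   HABITAT = as.integer(ss$suitable))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_statespace
#' @export
read_statespace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  if (!all(c("X", "Y", "HABITAT") %in% names(df))) {
    stop("format error: state-space file needs columns X, Y, HABITAT")
  }
  if (!all(df$HABITAT %in% c(0L, 1L))) {
    stop("format error: HABITAT values must be 0 or 1")
  }
  if (max(abs(c(df$X, df$Y))) > 1e4) {  # metres -> km
    df$X <- df$X * 1e-3
    df$Y <- df$Y * 1e-3
  }
  xs <- sort(unique(df$X))
  ys <- sort(unique(df$Y))
  dx <- diff(xs); dy <- diff(ys)
  spacing <- min(c(dx, dy))
  if (length(dx) && any(abs(dx / spacing - round(dx / spacing)) > 1e-6) ||
      length(dy) && any(abs(dy / spacing - round(dy / spacing)) > 1e-6)) {
    stop("state-space points do not form a regular grid")
  }
  if (nrow(df) != length(xs) * length(ys)) {
    stop("state-space file is not a complete rectangular mesh; mask ",
         "unsuitable points with HABITAT=0 rather than removing them")
  }
  ord <- order(df$Y, df$X)
  df <- df[ord, , drop = FALSE]
  structure(list(
    points = data.frame(x = df$X, y = df$Y),
    suitable = df$HABITAT == 1L,
    spacing = spacing,
    buffer = NA_real_,
    nx = length(xs), ny = length(ys),
    x0 = xs[1], y0 = ys[1]
  ), class = "camsecr_statespace")
}

# 8-neighbour adjacency on the suitable mesh, used by the sampler's local
# centre proposals. Returns a G x 8 integer matrix of 0-based suitable-point
# indices, -1 where the neighbouring cell is off-grid or unsuitable.
statespace_neighbours <- function(ss) {
  suit <- which(ss$suitable)
  G <- length(suit)
  col <- as.integer(round((ss$points$x[suit] - ss$x0) / ss$spacing))
  row <- as.integer(round((ss$points$y[suit] - ss$y0) / ss$spacing))
  gridid <- matrix(-1L, ss$ny, ss$nx)
  gridid[cbind(row + 1L, col + 1L)] <- seq_len(G) - 1L
  off <- cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  neigh <- matrix(-1L, G, 8L)
  for (k in 1:8) {
    r <- row + off[k, 1] + 1L
    c <- col + off[k, 2] + 1L
    ok <- r >= 1L & r <= ss$ny & c >= 1L & c <= ss$nx
    neigh[ok, k] <- gridid[cbind(r[ok], c[ok])]
  }
  neigh
}
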