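#' Single-molecule trajectory
#'
#' An ordered sequence of subpixel positions of one tracked molecule.
#' Coordinates follow the package-wide convention: micrometers, 0-based
#' frame indices, position (0, 0) at the center of the top-left pixel,
#' x rightward, y downward.
#'
#' @param track_id Identifier (coerced to character).
#' @param frames Integer frame indices, strictly increasing.
#' @param x,y Numeric positions in micrometers, finite.
#' @param intensity Optional per-frame counts (NULL if unavailable).
#' @return Object of class \code{trajectory}.
#' @export
trajectory <- function(track_id, frames, x, y, intensity = NULL) {
  frames <- as.integer(frames)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(frames)
  if (length(x) != n || length(y) != n)
    stop("frames, x, y must have equal length", call. = FALSE)
  if (n >= 2L && any(diff(frames) <= 0L))
    stop(sprintf("track '%s': frame indices must be strictly increasing",
                 track_id), call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop(sprintf("track '%s': non-finite position", track_id), call. = FALSE)
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != n)
      stop("intensity length must match frames", call. = FALSE)
  }
  structure(list(track_id = as.character(track_id), frames = frames,
                 x = x, y = y, intensity = intensity),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d frames [%d..%d]\n", x$track_id,
              length(x$frames), min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of localizations in a trajectory
#' @param traj A \code{trajectory}.
#' @return Integer count of frames.
#' @export
n_points <- function(traj) length(traj$frames)

#' Per-step displacement series of a trajectory
#'
#' Computes \eqn{\Delta x_k = x_{k+1} - x_k} and
#' \eqn{\Delta y_k = y_{k+1} - y_k} for a gap-free trajectory: a track of
#' N + 1 localizations yields N displacement steps.
#'
#' @param traj A \code{trajectory} with consecutive frames (no gaps).
#' @param dt Seconds per step (the frame interval).
#' @return Object of class \code{displacement_series} with fields
#'   \code{dx}, \code{dy} (micrometers) and \code{dt} (seconds).
#' @export
displacements <- function(traj, dt) {
  stopifnot(inherits(traj, "trajectory"), dt > 0)
  if (n_points(traj) < 2L)
    stop("need at least 2 localizations for displacements", call. = FALSE)
  if (any(diff(traj$frames) != 1L))
    stop(sprintf("track '%s' has frame gaps; displacements require consecutive frames",
                 traj$track_id), call. = FALSE)
  structure(list(dx = diff(traj$x), dy = diff(traj$y), dt = dt),
            class = "displacement_series")
}

#' Construct a displacement series directly
#'
#' Usually produced by \code{\link{displacements}}; the direct constructor
#' serves constructed fixtures and moment-level analyses.
#'
#' @param dx,dy Per-step displacements, micrometers (equal length).
#' @param dt Seconds per step.
#' @return Object of class \code{displacement_series}.
#' @export
displacement_series <- function(dx, dy, dt) {
  dx <- as.numeric(dx); dy <- as.numeric(dy)
  if (length(dx) != length(dy))
    stop("dx and dy must have equal length", call. = FALSE)
  stopifnot(dt > 0)
  structure(list(dx = dx, dy = dy, dt = dt),
            class = "displacement_series")
}

#' ROI polygon
#'
#' A simple (non-self-intersecting is the caller's responsibility) polygon
#' with at least 3 vertices, tagged with a label.
#'
#' @param vertices Two-column matrix of (x, y) vertex coordinates.
#' @param label Channel/compartment tag.
#' @param units Coordinate units, \code{"um"} or \code{"nm"}.
#' @return Object of class \code{roi_polygon}.
#' @export
roi_polygon <- function(vertices, label = "", units = c("nm", "um")) {
  units <- match.arg(units)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("ROI polygon needs >= 3 (x, y) vertices", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("ROI polygon has non-finite vertices", call. = FALSE)
  structure(list(vertices = unname(vertices), label = as.character(label),
                 units = units),
            class = "roi_polygon")
}
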