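#' Read linked trajectories from CSV
#'
#' Expects header columns \code{track_id,frame,x_um,y_um} and optionally
#' \code{intensity}. Rows are grouped by \code{track_id} and sorted by
#' frame; duplicate (track_id, frame) pairs are rejected.
#'
#' @param path CSV file path.
#' @param params Optional \code{acq_params}, attached as attribute.
#' @return List of \code{trajectory} objects, one per distinct track_id,
#'   in order of first appearance.
#' @export
read_trajectories <- function(path, params = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x_um", "y_um")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("trajectory CSV is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  has_int <- "intensity" %in% names(df)
  ids <- unique(as.character(df$track_id))
  out <- lapply(ids, function(id) {
    rows <- df[as.character(df$track_id) == id, , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    if (anyDuplicated(rows$frame))
      stop(sprintf("track '%s': duplicate frame index", id), call. = FALSE)
    trajectory(id, rows$frame, rows$x_um, rows$y_um,
               intensity = if (has_int) rows$intensity else NULL)
  })
  names(out) <- ids
  if (!is.null(params)) attr(out, "acq_params") <- params
  out
}

#' Write trajectories to CSV
#'
#' Positions are written with 6 decimal places (micrometers), so a
#' write/read cycle round-trips the text representation exactly.
#'
#' @param trajs List of \code{trajectory} objects.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    d <- data.frame(track_id = tr$track_id, frame = tr$frames,
                    x_um = sprintf("%.6f", tr$x),
                    y_um = sprintf("%.6f", tr$y),
                    stringsAsFactors = FALSE)
    if (!is.null(tr$intensity)) d$intensity <- sprintf("%.3f", tr$intensity)
    d
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary synapse mask from TIFF
#'
#' Reads a single-page 8-bit TIFF; any nonzero pixel is synaptic. The mask
#' shares the trajectory coordinate convention (pixel centers at integer
#' multiples of \code{pixel_size}, origin at the top-left pixel center).
#'
#' @param path Single-page TIFF path.
#' @param pixel_size Micrometers per pixel.
#' @return Object of class \code{synapse_mask}: logical occupancy matrix
#'   (rows = y, cols = x), pixel size and origin offset.
#' @export
read_mask <- function(path, pixel_size) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) != 1L)
    stop("multi-page mask TIFF: apply project_mask_stack() first",
         call. = FALSE)
  synapse_mask(img[[1]] > 0, pixel_size = pixel_size)
}

#' Construct a synapse mask object
#'
#' @param occupancy Logical (or 0/1) matrix; TRUE/nonzero = synaptic.
#'   Rows index y (downward), columns index x (rightward).
#' @param pixel_size Micrometers per pixel.
#' @param origin Physical (x, y) of the top-left pixel center, micrometers.
#' @return Object of class \code{synapse_mask}.
#' @export
synapse_mask <- function(occupancy, pixel_size, origin = c(0, 0)) {
  occupancy <- as.matrix(occupancy)
  stopifnot(length(occupancy) >= 1L, pixel_size > 0, length(origin) == 2L)
  structure(list(occupancy = matrix(occupancy != 0, nrow(occupancy)),
                 pixel_size = pixel_size, origin = as.numeric(origin)),
            class = "synapse_mask")
}

#' Total synaptic area of a mask
#' @param mask A \code{synapse_mask}.
#' @return Area in square micrometers.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "synapse_mask"))
  sum(mask$occupancy) * mask$pixel_size^2
}

#' Write a synapse mask as an 8-bit TIFF
#' @param mask A \code{synapse_mask}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "synapse_mask"))
  tiff::writeTIFF(ifelse(mask$occupancy, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a 3D STORM localization cloud from CSV
#'
#' Expects columns \code{x_nm,y_nm,z_nm,photons,channel}. Coordinates are
#' nanometers throughout the STORM module.
#'
#' @param path CSV file path.
#' @return Object of class \code{storm_cloud}.
#' @export
read_storm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("x_nm", "y_nm", "z_nm", "photons", "channel")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("STORM CSV is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  storm_cloud(cbind(df$x_nm, df$y_nm, df$z_nm), df$photons, df$channel)
}

#' Construct a STORM localization cloud
#'
#' @param points n-by-3 matrix of (x, y, z) in nanometers (0-row allowed).
#' @param photons Per-point photon counts, nonnegative.
#' @param channel Per-point channel labels.
#' @return Object of class \code{storm_cloud}.
#' @export
storm_cloud <- function(points, photons = numeric(0), channel = character(0)) {
  points <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(points)
  if (n > 0L && any(!is.finite(points)))
    stop("STORM cloud has non-finite coordinates", call. = FALSE)
  photons <- as.numeric(photons)
  if (length(photons) == 0L) photons <- rep(0, n)
  if (length(photons) != n)
    stop("photons length must match point count", call. = FALSE)
  if (any(photons < 0))
    stop("negative photon count in STORM cloud", call. = FALSE)
  channel <- as.character(channel)
  if (length(channel) == 0L) channel <- rep("1", n)
  if (length(channel) != n)
    stop("channel length must match point count", call. = FALSE)
  structure(list(points = unname(points), photons = photons,
                 channel = channel),
            class = "storm_cloud")
}

#' @export
print.storm_cloud <- function(x, ...) {
  cat(sprintf("STORM cloud: %d localizations, %d channel(s)\n",
              nrow(x$points), length(unique(x$channel))))
  invisible(x)
}

#' Write a STORM cloud to CSV (2 decimal places, nanometers)
#' @param cloud A \code{storm_cloud}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_storm_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "storm_cloud"))
  df <- data.frame(x_nm = sprintf("%.2f", cloud$points[, 1]),
                   y_nm = sprintf("%.2f", cloud$points[, 2]),
                   z_nm = sprintf("%.2f", cloud$points[, 3]),
                   photons = cloud$photons, channel = cloud$channel,
                   stringsAsFactors = FALSE)
  if (nrow(cloud$points) == 0L)
    df <- df[0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ROI polygons from JSON
#'
#' Expects a JSON list of objects with a \code{label} and either
#' \code{vertices_um} or \code{vertices_nm}, an array of [x, y] pairs.
#'
#' @param path JSON file path.
#' @return List of \code{roi_polygon} objects.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    key <- intersect(c("vertices_um", "vertices_nm"), names(r))
    key <- key[!vapply(r[key], is.null, logical(1))]
    if (length(key) != 1L)
      stop("ROI entry needs exactly one of vertices_um / vertices_nm",
           call. = FALSE)
    v <- do.call(rbind, lapply(r[[key]], unlist))
    roi_polygon(v, label = r$label %||% "",
                units = if (key == "vertices_um") "um" else "nm")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration file
#'
#' A single YAML file holds every threshold and parameter of a run so the
#' analysis is reproducible from the file plus a seed.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Hash of a configuration for run logging
#' @param config Named list as returned by \code{read_config}.
#' @return Character hash of the canonical serialization.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the canonical JSON text, hex-encoded
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 35184372088832  # 2^45: keeps h*131 exact in doubles
  sprintf("%012.0f", h)
}
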