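# Synaptic classification of receptor trajectories against a binary
# presynaptic (mitochondria-stain derived) mask, dwell times, and the
# synaptic fraction of tracked molecules.

#' Project a mask time-lapse stack to a binary synapse mask
#'
#' Pixelwise average- or maximum-intensity Z-projection of a time-lapse
#' stack, binarized at \code{threshold} times the projected maximum.
#'
#' @param stack List of numeric frame matrices (>= 1 frame).
#' @param mode \code{"max"} (default) or \code{"average"}.
#' @param threshold Binarization level as a fraction of the projected
#'   maximum (default 0.5).
#' @param pixel_size Micrometers per pixel.
#' @return A \code{synapse_mask}; the projection mode and threshold are
#'   stored in attributes \code{"mode"} and \code{"threshold"}.
#' @export
project_mask_stack <- function(stack, mode = c("max", "average"),
                               threshold = 0.5, pixel_size = 0.16) {
  mode <- match.arg(mode)
  if (length(stack) == 0L) stop("empty mask stack", call. = FALSE)
  proj <- Reduce(if (mode == "max") pmax else `+`, stack)
  if (mode == "average") proj <- proj / length(stack)
  mx <- max(proj)
  occ <- if (mx > 0) proj >= threshold * mx else proj > 0
  out <- synapse_mask(occ, pixel_size)
  attr(out, "mode") <- mode
  attr(out, "threshold") <- threshold
  out
}

# 0-based pixel indices containing physical positions (pixel-center origin)
position_pixel <- function(x, y, mask) {
  list(col = floor((x - mask$origin[1]) / mask$pixel_size + 0.5),
       row = floor((y - mask$origin[2]) / mask$pixel_size + 0.5))
}

#' Classify one trajectory as synaptic or extrasynaptic
#'
#' A frame is "inside" iff the pixel containing the position is synaptic;
#' the trajectory is synaptic iff it colocalizes with the mask on at least
#' one frame. Positions outside the mask bounds count as outside (their
#' number is reported).
#'
#' @param traj A \code{trajectory} (same coordinate frame as the mask).
#' @param mask A \code{synapse_mask}.
#' @param frame_interval Seconds per frame, for the dwell time.
#' @return One-row data.frame: \code{track_id}, \code{label}
#'   ("synaptic"/"extrasynaptic"), \code{frames_inside},
#'   \code{dwell_time} (seconds, frames_inside x frame_interval),
#'   \code{visits} (maximal runs of consecutive inside frames),
#'   \code{n_out_of_bounds}.
#' @export
classify_trajectory <- function(traj, mask, frame_interval) {
  stopifnot(inherits(traj, "trajectory"), inherits(mask, "synapse_mask"),
            frame_interval > 0)
  px <- position_pixel(traj$x, traj$y, mask)
  nr <- nrow(mask$occupancy); nc <- ncol(mask$occupancy)
  in_bounds <- px$col >= 0L & px$col < nc & px$row >= 0L & px$row < nr
  inside <- logical(length(traj$x))
  inside[in_bounds] <- mask$occupancy[cbind(px$row[in_bounds] + 1L,
                                            px$col[in_bounds] + 1L)]
  n_oob <- sum(!in_bounds)
  if (n_oob > 0L)
    warning(sprintf("track '%s': %d position(s) outside mask bounds, treated as extrasynaptic",
                    traj$track_id, n_oob), call. = FALSE)
  runs <- rle(inside)
  data.frame(track_id = traj$track_id,
             label = if (any(inside)) "synaptic" else "extrasynaptic",
             frames_inside = sum(inside),
             dwell_time = sum(inside) * frame_interval,
             visits = sum(runs$values),
             n_out_of_bounds = n_oob,
             stringsAsFactors = FALSE)
}

#' Classify a set of trajectories against a synapse mask
#'
#' @param trajs List of \code{trajectory} objects.
#' @param mask A \code{synapse_mask}.
#' @param frame_interval Seconds per frame.
#' @return data.frame with one row per track (see
#'   \code{\link{classify_trajectory}}).
#' @export
classify_tracks <- function(trajs, mask, frame_interval) {
  do.call(rbind, c(lapply(trajs, classify_trajectory, mask = mask,
                          frame_interval = frame_interval),
                   list(make.row.names = FALSE)))
}

#' Mean synaptic dwell time over synaptic tracks
#'
#' Dwell time per synaptic receptor is its total inside-time
#' (frames_inside x frame_interval); the summary is mean and SEM over
#' synaptic tracks only.
#'
#' @param results data.frame from \code{\link{classify_tracks}}.
#' @param frame_interval Seconds per frame (recomputes dwell from
#'   frames_inside so the summary is unit-consistent).
#' @return List: \code{n} (synaptic tracks), \code{mean_dwell} (s),
#'   \code{sem_dwell} (0 with a \code{single_track} flag when n = 1),
#'   \code{per_track} (dwell times). Empty result with a warning when no
#'   track is synaptic.
#' @export
dwell_time_summary <- function(results, frame_interval) {
  stopifnot(is.data.frame(results), frame_interval > 0)
  syn <- results[results$label == "synaptic", , drop = FALSE]
  if (nrow(syn) == 0L) {
    warning("no synaptic tracks; dwell-time summary empty", call. = FALSE)
    return(list(n = 0L, mean_dwell = NA_real_, sem_dwell = NA_real_,
                single_track = FALSE, per_track = numeric(0)))
  }
  dwell <- syn$frames_inside * frame_interval
  n <- length(dwell)
  list(n = n,
       mean_dwell = mean(dwell),
       sem_dwell = if (n > 1L) stats::sd(dwell) / sqrt(n) else 0,
       single_track = n == 1L,
       per_track = dwell)
}

#' Synaptic fraction of tracked molecules
#'
#' Relative synaptic content of a recording: synaptic / total trajectories.
#'
#' @param results data.frame from \code{\link{classify_tracks}} (>= 1 row).
#' @return Fraction in [0, 1].
#' @export
synaptic_content <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  mean(results$label == "synaptic")
}
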