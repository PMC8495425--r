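# Synthetic-data generators. The motion simulator builds blur mechanistically
# (averaging sub-positions over the exposure) rather than sampling the
# analysis model's covariance, so the estimator is tested against physics
# rather than against itself.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state.
#' With \code{seed = NULL} the expression runs on the current RNG stream.
#'
#' @param seed Integer seed or NULL.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Motion model for trajectory simulation
#'
#' @param kind \code{"brownian"} (free diffusion) or \code{"confined"}
#'   (reflecting square corral of side \code{domain_size} centered on
#'   \code{start}).
#' @param D_true Diffusion coefficient, square micrometers per second.
#' @param domain_size Side of the square corral, micrometers (confined only).
#' @param start Starting (x, y), micrometers.
#' @return Object of class \code{motion_model}.
#' @export
motion_model <- function(kind = c("brownian", "confined"), D_true,
                         domain_size = NULL, start = c(0, 0)) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(D_true), length(D_true) == 1L, D_true >= 0)
  if (kind == "confined") {
    if (is.null(domain_size) || domain_size <= 0)
      stop("confined motion needs `domain_size` > 0", call. = FALSE)
  }
  structure(list(kind = kind, D_true = D_true, domain_size = domain_size,
                 start = as.numeric(start)),
            class = "motion_model")
}

# fold a free path into [lo, hi] (method of images for reflected diffusion)
reflect_fold <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y < w, y, 2 * w - y)
}

#' Simulate one observed trajectory with motion blur and localization noise
#'
#' Within each exposure of length E, the molecule is propagated through
#' \code{n_substeps} Brownian sub-steps (positions sampled at sub-step
#' midpoints) and the camera observes their average — the mechanistic form
#' of motion blur under continuous illumination. Independent Gaussian
#' localization noise of sd \code{sigma_loc} is then added per axis. If the
#' frame interval exceeds the exposure, the dark gap is simulated but not
#' observed. Confined motion reflects at the corral boundary.
#'
#' With \code{n_substeps = 1} the observation is a point sample (blur
#' coefficient R = 0); as \code{n_substeps} grows the displacement
#' covariance converges to the analysis model with R = 1/6.
#'
#' @param model A \code{motion_model}.
#' @param acq An \code{acq_params}.
#' @param n_frames Number of frames (>= 2).
#' @param n_substeps Sub-steps per exposure (>= 1, default 50).
#' @param sigma_loc Static localization noise sd, micrometers (>= 0).
#' @param seed Integer seed or NULL.
#' @param track_id Identifier for the observed trajectory.
#' @return List with \code{observed} (a \code{trajectory}), \code{true}
#'   (frame-averaged true positions, noise-free, as a \code{trajectory}),
#'   and \code{subpos} (per-frame matrices of true sub-positions, for
#'   movie rendering).
#' @export
simulate_trajectory <- function(model, acq, n_frames, n_substeps = 50L,
                                sigma_loc = 0, seed = NULL,
                                track_id = "sim") {
  stopifnot(inherits(model, "motion_model"), inherits(acq, "acq_params"))
  n_frames <- as.integer(n_frames); n_substeps <- as.integer(n_substeps)
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (n_substeps < 1L) stop("n_substeps must be >= 1", call. = FALSE)
  if (!is.finite(sigma_loc) || sigma_loc < 0)
    stop("sigma_loc must be nonnegative", call. = FALSE)
  with_seed(seed, {
    E <- acq$exposure; dT <- acq$frame_interval
    tau <- E / n_substeps
    # time gaps between consecutive sampled sub-positions (midpoint scheme):
    # half sub-step into the first exposure, then full sub-steps within each
    # exposure, with the dark gap folded into the frame-to-frame jump
    gaps <- c(tau / 2,
              rep(c(rep(tau, n_substeps - 1L), dT - E + tau),
                  n_frames - 1L),
              rep(tau, n_substeps - 1L))
    m <- length(gaps)  # n_frames * n_substeps sampled sub-positions
    sd_step <- sqrt(2 * model$D_true * gaps)
    px <- model$start[1] + cumsum(stats::rnorm(m, 0, sd_step))
    py <- model$start[2] + cumsum(stats::rnorm(m, 0, sd_step))
    if (model$kind == "confined") {
      half <- model$domain_size / 2
      px <- reflect_fold(px, model$start[1] - half, model$start[1] + half)
      py <- reflect_fold(py, model$start[2] - half, model$start[2] + half)
    }
    fidx <- rep(seq_len(n_frames), each = n_substeps)
    tx <- colMeans(matrix(px, nrow = n_substeps))
    ty <- colMeans(matrix(py, nrow = n_substeps))
    ox <- tx + stats::rnorm(n_frames, 0, sigma_loc)
    oy <- ty + stats::rnorm(n_frames, 0, sigma_loc)
    frames <- 0:(n_frames - 1L)
    rows <- split(seq_len(m), fidx)
    subpos <- lapply(rows, function(i) cbind(px[i], py[i]))
    names(subpos) <- NULL
    list(observed = trajectory(track_id, frames, ox, oy),
         true = trajectory(paste0(track_id, "_true"), frames, tx, ty),
         subpos = subpos)
  })
}

#' Simulate an ensemble of observed trajectories
#'
#' Convenience wrapper around \code{\link{simulate_trajectory}} drawing
#' \code{n_tracks} independent tracks on one RNG stream.
#'
#' @inheritParams simulate_trajectory
#' @param n_tracks Number of trajectories.
#' @param id_prefix Prefix for track identifiers.
#' @return List of \code{trajectory} objects (the observed tracks).
#' @export
simulate_ensemble <- function(n_tracks, model, acq, n_frames,
                              n_substeps = 50L, sigma_loc = 0,
                              seed = NULL, id_prefix = "sim") {
  with_seed(seed, {
    lapply(seq_len(n_tracks), function(i)
      simulate_trajectory(model, acq, n_frames, n_substeps, sigma_loc,
                          seed = NULL,
                          track_id = sprintf("%s%04d", id_prefix, i))$observed)
  })
}

#' Camera model for movie rendering
#'
#' @param psf_sigma Gaussian PSF sd, micrometers.
#' @param counts_per_molecule Expected photon counts per molecule per frame.
#' @param background Background level, counts per pixel.
#' @param read_noise_sd Gaussian read noise sd, counts (0 disables).
#' @param image_shape Integer (rows, cols) = (ny, nx) pixels.
#' @param shot_noise Apply Poisson photon noise? Default TRUE.
#' @return Object of class \code{camera_model}.
#' @export
camera_model <- function(psf_sigma, counts_per_molecule, background = 0,
                         read_noise_sd = 0, image_shape = c(32L, 32L),
                         shot_noise = TRUE) {
  stopifnot(psf_sigma > 0, counts_per_molecule >= 0, background >= 0,
            read_noise_sd >= 0, length(image_shape) == 2L)
  structure(list(psf_sigma = psf_sigma,
                 counts_per_molecule = counts_per_molecule,
                 background = background, read_noise_sd = read_noise_sd,
                 image_shape = as.integer(image_shape),
                 shot_noise = isTRUE(shot_noise)),
            class = "camera_model")
}

# expected photon image of one PSF centered at (x0, y0) um, integrated over
# pixels (error-function model of a symmetric Gaussian)
psf_pixel_image <- function(x0, y0, total_counts, psf_sigma, pixel_size,
                            shape) {
  ny <- shape[1]; nx <- shape[2]; s <- psf_sigma
  ex <- stats::pnorm((((0:nx) - 0.5) * pixel_size - x0) / s)
  ey <- stats::pnorm((((0:ny) - 0.5) * pixel_size - y0) / s)
  total_counts * outer(diff(ey), diff(ex))
}

#' Render a synthetic fluorescence movie
#'
#' Each frame is the sum, over molecules and their within-exposure
#' sub-positions, of a pixel-integrated symmetric Gaussian PSF, plus uniform
#' background, optional Poisson shot noise and Gaussian read noise. Output
#' values are clamped to [0, 65535] (16-bit writable).
#'
#' @param paths List over molecules; each element a list over frames of
#'   k-by-2 matrices of true sub-positions in micrometers (the
#'   \code{subpos} field of \code{\link{simulate_trajectory}}), or a
#'   single n_frames-by-2 matrix of static per-frame positions.
#' @param cam A \code{camera_model}.
#' @param acq An \code{acq_params} (supplies the pixel size).
#' @param n_frames Number of frames (inferred from paths when NULL).
#' @param seed Integer seed or NULL.
#' @return List of numeric matrices (counts), one per frame.
#' @export
render_movie <- function(paths, cam, acq, n_frames = NULL, seed = NULL) {
  stopifnot(inherits(cam, "camera_model"), inherits(acq, "acq_params"))
  paths <- lapply(paths, function(p) {
    if (is.matrix(p)) lapply(seq_len(nrow(p)), function(i) p[i, , drop = FALSE])
    else p
  })
  if (is.null(n_frames))
    n_frames <- if (length(paths)) length(paths[[1]]) else
      stop("n_frames required when no molecules given", call. = FALSE)
  shape <- cam$image_shape; px <- acq$pixel_size
  xmax <- (shape[2] - 1) * px; ymax <- (shape[1] - 1) * px
  clipped <- FALSE
  with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      img <- matrix(cam$background, shape[1], shape[2])
      for (mol in paths) {
        sp <- mol[[f]]
        if (is.null(sp) || nrow(sp) == 0L) next
        if (any(sp[, 1] < -0.5 * px) || any(sp[, 1] > xmax + 0.5 * px) ||
            any(sp[, 2] < -0.5 * px) || any(sp[, 2] > ymax + 0.5 * px)) {
          if (!clipped) warning("molecule outside frame: contribution clipped",
                                call. = FALSE)
          clipped <<- TRUE
        }
        cpp <- cam$counts_per_molecule / nrow(sp)
        for (i in seq_len(nrow(sp)))
          img <- img + psf_pixel_image(sp[i, 1], sp[i, 2], cpp,
                                       cam$psf_sigma, px, shape)
      }
      if (cam$shot_noise)
        img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                      shape[1], shape[2])
      if (cam$read_noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, cam$read_noise_sd),
                            shape[1], shape[2])
      pmin(pmax(img, 0), 65535)
    })
  })
}

#' Write a movie as a 16-bit multi-page TIFF
#' @param movie List of numeric frame matrices (counts in [0, 65535]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(movie, path) {
  tiff::writeTIFF(lapply(movie, function(fr) round(fr) / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF movie into count matrices
#' @param path TIFF path.
#' @return List of numeric matrices (counts).
#' @export
read_movie <- function(path) {
  lapply(tiff::readTIFF(path, all = TRUE), function(fr) fr * 65535)
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' Piecewise-constant trace starting at \code{n_steps * level}, dropping by
#' \code{level} at each bleach frame (one fluorophore lost per step), with
#' additive Gaussian noise.
#'
#' @param n_steps Number of active fluorophores (= number of bleach steps).
#' @param level Counts contributed by one fluorophore.
#' @param bleach_frames Increasing frame indices of the bleach events,
#'   length \code{n_steps}, each < \code{n_frames}.
#' @param noise_sd Gaussian noise sd, counts.
#' @param n_frames Trace length.
#' @param seed Integer seed or NULL.
#' @return Object of class \code{intensity_trace} (fields \code{values},
#'   \code{frames}).
#' @export
simulate_bleach_trace <- function(n_steps, level, bleach_frames, noise_sd,
                                  n_frames, seed = NULL) {
  n_steps <- as.integer(n_steps)
  bleach_frames <- as.integer(bleach_frames)
  if (length(bleach_frames) != n_steps)
    stop("length(bleach_frames) must equal n_steps", call. = FALSE)
  if (n_steps > 0L && (any(diff(bleach_frames) <= 0L) && n_steps > 1L))
    stop("bleach_frames must be strictly increasing", call. = FALSE)
  if (any(bleach_frames >= n_frames) || any(bleach_frames < 0L))
    stop("bleach frame outside [0, n_frames)", call. = FALSE)
  with_seed(seed, {
    frames <- 0:(n_frames - 1L)
    active <- n_steps - vapply(frames, function(f)
      sum(bleach_frames <= f), integer(1))
    values <- active * level + stats::rnorm(n_frames, 0, noise_sd)
    intensity_trace(values, frames)
  })
}

#' Intensity trace of one spot or track
#' @param values Per-frame counts.
#' @param frames Frame indices (same length).
#' @return Object of class \code{intensity_trace}.
#' @export
intensity_trace <- function(values, frames = seq_along(values) - 1L) {
  if (length(values) != length(frames))
    stop("values and frames must align", call. = FALSE)
  structure(list(values = as.numeric(values), frames = as.integer(frames)),
            class = "intensity_trace")
}

#' Rasterize disk-shaped synapses into a binary mask
#'
#' A pixel is synaptic iff its center lies within \code{radius} of any
#' synapse center.
#'
#' @param centers k-by-2 matrix of synapse centers (x, y), micrometers
#'   (0-row matrix allowed).
#' @param radius Disk radius, micrometers (> 0).
#' @param shape Integer (rows, cols) of the mask.
#' @param pixel_size Micrometers per pixel.
#' @return A \code{synapse_mask}.
#' @export
make_synapse_mask <- function(centers, radius, shape, pixel_size) {
  stopifnot(radius > 0, length(shape) == 2L, pixel_size > 0)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  occ <- matrix(FALSE, ny, nx)
  if (nrow(centers) > 0L) {
    xs <- (0:(nx - 1L)) * pixel_size
    ys <- (0:(ny - 1L)) * pixel_size
    for (k in seq_len(nrow(centers))) {
      d2 <- outer((ys - centers[k, 2])^2, (xs - centers[k, 1])^2, `+`)
      occ <- occ | (d2 <= radius^2)
    }
  }
  synapse_mask(occ, pixel_size)
}

#' Simulate a clustered 3D STORM localization cloud
#'
#' Cluster centers are uniform in the square field laterally and uniform
#' in the central part of \code{z_range} axially (optionally
#' rejection-sampled to a minimum pairwise lateral separation); member
#' points are isotropic 3D Gaussian around their center, with z reflected
#' back into \code{z_range} (the detectable axial band); background points
#' are uniform in the field and in \code{z_range}.
#'
#' @param n_clusters Number of molecule clusters.
#' @param pts_per_cluster Mean localizations per cluster (Poisson,
#'   truncated below at \code{min_pts}).
#' @param cluster_sd Isotropic sd of member points around the center, nm.
#' @param field Side of the square field, nm.
#' @param background_pts Number of uniform background localizations.
#' @param z_range Axial range (z_min, z_max), nm. Default c(-300, 300).
#' @param channel Channel label for every point.
#' @param min_pts Minimum localizations per cluster (default 1).
#' @param min_separation Minimum pairwise center distance, nm (default 0).
#' @param photons_mean Mean photon count per localization (Poisson).
#' @param seed Integer seed or NULL.
#' @return List with \code{cloud} (a \code{storm_cloud}), \code{labels}
#'   (true cluster index per point, 0 = background) and \code{centers}
#'   (true cluster centers, n_clusters-by-3 nm).
#' @export
simulate_storm_cloud <- function(n_clusters, pts_per_cluster, cluster_sd,
                                 field = 5000, background_pts = 0,
                                 z_range = c(-300, 300), channel = "1",
                                 min_pts = 1L, min_separation = 0,
                                 photons_mean = 1000, seed = NULL) {
  stopifnot(cluster_sd > 0 || n_clusters == 0, field > 0)
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 3)
    if (n_clusters > 0L) {
      # keep cluster cores away from the band edges so members stay inside
      z_pad <- min(3 * cluster_sd, diff(z_range) / 2)
      repeat {
        centers <- cbind(stats::runif(n_clusters, 0, field),
                         stats::runif(n_clusters, 0, field),
                         stats::runif(n_clusters, z_range[1] + z_pad,
                                      z_range[2] - z_pad))
        if (n_clusters == 1L || min_separation <= 0 ||
            min(stats::dist(centers[, 1:2])) >= min_separation) break
      }
    }
    xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
    labels <- integer(0)
    for (k in seq_len(n_clusters)) {
      m <- max(min_pts, stats::rpois(1, pts_per_cluster))
      xs <- c(xs, stats::rnorm(m, centers[k, 1], cluster_sd))
      ys <- c(ys, stats::rnorm(m, centers[k, 2], cluster_sd))
      zs <- c(zs, reflect_fold(stats::rnorm(m, centers[k, 3], cluster_sd),
                               z_range[1], z_range[2]))
      labels <- c(labels, rep(k, m))
    }
    if (background_pts > 0L) {
      xs <- c(xs, stats::runif(background_pts, 0, field))
      ys <- c(ys, stats::runif(background_pts, 0, field))
      zs <- c(zs, stats::runif(background_pts, z_range[1], z_range[2]))
      labels <- c(labels, rep(0L, background_pts))
    }
    n <- length(xs)
    cloud <- storm_cloud(cbind(xs, ys, zs),
                         photons = stats::rpois(n, photons_mean),
                         channel = rep(channel, n))
    list(cloud = cloud, labels = labels, centers = centers)
  })
}
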