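# From movie frames to quality-filtered trajectories: bandpass spot
# detection, subpixel 2D Gaussian localization, intensity-trace
# validation (stepwise photobleaching, lognormal intensity histogram),
# minimum-step linking, and track filtering.

# separable convolution with replicate padding
conv_sep <- function(img, kernel) {
  k <- length(kernel); r <- (k - 1L) %/% 2L
  pad_apply <- function(m) {
    nr <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nr, r), , drop = FALSE])
    out <- matrix(0, nr, ncol(m))
    for (i in seq_len(k))
      out <- out + kernel[i] * mp[i:(i + nr - 1L), , drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(img))))
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# square max filter of half-width r via separable running max
max_filter <- function(img, r) {
  shift_max_1d <- function(m) {
    out <- m
    nr <- nrow(m)
    for (s in seq_len(r)) {
      up <- m[c((1L + s):nr, rep(nr, s)), , drop = FALSE]
      dn <- m[c(rep(1L, s), 1L:(nr - s)), , drop = FALSE]
      out <- pmax(out, up, dn)
    }
    out
  }
  t(shift_max_1d(t(shift_max_1d(img))))
}

#' Detect candidate spots in a single frame
#'
#' Band-passes the frame with a difference of Gaussians, estimates the
#' noise sd robustly (MAD), and returns local maxima exceeding
#' \code{min_snr} times that sd. Maxima within one detection window merge
#' (non-maximum suppression) and candidates closer than \code{window / 2}
#' pixels to an edge are discarded.
#'
#' @param frame Numeric image matrix (rows = y, cols = x).
#' @param min_snr Detection threshold in units of background noise sd.
#' @param window Odd suppression/fitting window, pixels (default 7).
#' @param sigma_small,sigma_large DoG scales, pixels.
#' @return data.frame with 0-based pixel coordinates \code{x_px},
#'   \code{y_px} and the band-passed \code{response}; 0 rows when nothing
#'   is found.
#' @export
detect_spots <- function(frame, min_snr = 5, window = 7L,
                         sigma_small = 1, sigma_large = 3) {
  stopifnot(is.matrix(frame), window >= 3L)
  bp <- conv_sep(frame, gauss_kernel(sigma_small)) -
    conv_sep(frame, gauss_kernel(sigma_large))
  noise_sd <- stats::mad(bp)
  r <- as.integer(window) %/% 2L
  mx <- max_filter(bp, r)
  is_peak <- bp >= mx & bp > min_snr * noise_sd
  if (noise_sd == 0) is_peak <- bp >= mx & bp > 0
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x_px = integer(0), y_px = integer(0),
                      response = numeric(0)))
  keep <- idx[, 1] > r & idx[, 1] <= nrow(frame) - r &
    idx[, 2] > r & idx[, 2] <= ncol(frame) - r
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) > 1L) {
    # tied plateau maxima: keep one candidate per suppression window
    resp <- bp[idx]
    ord <- order(-resp, idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    kept <- logical(nrow(idx))
    for (i in seq_len(nrow(idx))) {
      sel <- which(kept)
      if (!length(sel) ||
          all(pmax(abs(idx[sel, 1] - idx[i, 1]),
                   abs(idx[sel, 2] - idx[i, 2])) > r))
        kept[i] <- TRUE
    }
    idx <- idx[kept, , drop = FALSE]
  }
  data.frame(x_px = idx[, 2] - 1L, y_px = idx[, 1] - 1L,
             response = bp[idx])
}

#' Subpixel localization by 2D Gaussian least squares
#'
#' Fits \eqn{A \exp(-((x - x_0)^2 + (y - y_0)^2) / (2 s^2)) + b} to a
#' square patch around a candidate pixel by nonlinear least squares and
#' returns the center in physical units. \code{fit_ok} is FALSE when the
#' optimizer fails, the amplitude is nonpositive, the fitted width leaves
#' (0.5, 5) px, or the center leaves the patch.
#'
#' @param patch Square numeric matrix (side >= 5, odd) centered on the
#'   candidate pixel.
#' @param center_px 0-based (x, y) pixel index of the patch center in the
#'   full image.
#' @param pixel_size Micrometers per pixel.
#' @param frame Frame index to record (default NA).
#' @return A one-row data.frame: \code{frame}, \code{x_um}, \code{y_um},
#'   \code{intensity} (integrated counts above background,
#'   \eqn{2\pi A s^2}), \code{psf_sigma_um}, \code{background},
#'   \code{fit_ok}.
#' @export
fit_gaussian_2d <- function(patch, center_px, pixel_size, frame = NA_integer_) {
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch),
            nrow(patch) >= 5L, pixel_size > 0)
  if (any(!is.finite(patch)))
    stop("patch contains non-finite values", call. = FALSE)
  side <- nrow(patch)
  half <- (side - 1L) / 2
  xs <- seq_len(side) - 1 - half   # patch pixel offsets from center
  ys <- xs
  xg <- matrix(xs, side, side, byrow = TRUE)
  yg <- matrix(ys, side, side)
  b0 <- stats::median(patch)
  A0 <- max(patch) - b0
  pk <- which(patch == max(patch), arr.ind = TRUE)[1, ]
  bad <- function() data.frame(frame = frame, x_um = NA_real_, y_um = NA_real_,
                               intensity = NA_real_, psf_sigma_um = NA_real_,
                               background = NA_real_, fit_ok = FALSE)
  if (A0 <= 0) return(bad())
  ssq <- function(par) {
    mu <- par[4] * exp(-((xg - par[1])^2 + (yg - par[2])^2) /
                         (2 * exp(2 * par[3]))) + par[5]
    sum((patch - mu)^2)
  }
  init <- c(xs[pk[2]], ys[pk[1]], log(1.3), A0, b0)
  fit <- tryCatch(
    stats::optim(init, ssq, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad())
  x0 <- fit$par[1]; y0 <- fit$par[2]; s <- exp(fit$par[3])
  A <- fit$par[4]; b <- fit$par[5]
  ok <- fit$convergence == 0L && A > 0 && s > 0.5 && s < 5 &&
    abs(x0) <= half && abs(y0) <= half
  data.frame(frame = frame,
             x_um = (center_px[1] + x0) * pixel_size,
             y_um = (center_px[2] + y0) * pixel_size,
             intensity = 2 * pi * A * s^2,
             psf_sigma_um = s * pixel_size,
             background = b,
             fit_ok = ok)
}

#' Detect and localize spots in every frame of a movie
#'
#' @param movie List of frame matrices (counts).
#' @param acq An \code{acq_params} (pixel size).
#' @param min_snr,window Passed to \code{\link{detect_spots}}.
#' @return data.frame of localizations (columns as in
#'   \code{\link{fit_gaussian_2d}}), 0-based frames, failed fits dropped.
#' @export
localize_movie <- function(movie, acq, min_snr = 5, window = 7L) {
  stopifnot(inherits(acq, "acq_params"))
  half <- as.integer(window) %/% 2L
  rows <- lapply(seq_along(movie), function(f) {
    fr <- movie[[f]]
    cand <- detect_spots(fr, min_snr = min_snr, window = window)
    if (nrow(cand) == 0L) return(NULL)
    fits <- lapply(seq_len(nrow(cand)), function(i) {
      r0 <- cand$y_px[i] + 1L; c0 <- cand$x_px[i] + 1L
      patch <- fr[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
      fit_gaussian_2d(patch, c(cand$x_px[i], cand$y_px[i]),
                      acq$pixel_size, frame = f - 1L)
    })
    do.call(rbind, fits)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      psf_sigma_um = numeric(0), background = numeric(0),
                      fit_ok = logical(0)))
  out[out$fit_ok, , drop = FALSE]
}

#' Extract a background-subtracted intensity trace along a trajectory
#'
#' Per frame, sums the counts in a disk of \code{radius} pixels around the
#' tracked position and subtracts the frame's median background times the
#' disk area.
#'
#' @param movie List of frame matrices.
#' @param traj A \code{trajectory} (frames must index into the movie).
#' @param radius Disk radius, pixels.
#' @param pixel_size Micrometers per pixel.
#' @return An \code{intensity_trace}.
#' @export
extract_intensity_trace <- function(movie, traj, radius, pixel_size) {
  stopifnot(inherits(traj, "trajectory"), radius > 0)
  if (any(traj$frames < 0L) || any(traj$frames >= length(movie)))
    stop("trajectory frame index beyond movie stack", call. = FALSE)
  values <- vapply(seq_along(traj$frames), function(i) {
    fr <- movie[[traj$frames[i] + 1L]]
    cx <- traj$x[i] / pixel_size  # 0-based pixel coordinates
    cy <- traj$y[i] / pixel_size
    cols <- which(abs(seq_len(ncol(fr)) - 1 - cx) <= radius)
    rws <- which(abs(seq_len(nrow(fr)) - 1 - cy) <= radius)
    sub <- fr[rws, cols, drop = FALSE]
    d2 <- outer((rws - 1 - cy)^2, (cols - 1 - cx)^2, `+`)
    inside <- d2 <= radius^2
    sum(sub[inside]) - sum(inside) * stats::median(fr)
  }, numeric(1))
  intensity_trace(values, traj$frames)
}

#' Count downward photobleaching steps in an intensity trace
#'
#' Least-squares piecewise-constant segmentation by recursive binary
#' splitting: a split is accepted iff it reduces the residual sum of
#' squares by more than \code{penalty} times a robust noise-variance
#' estimate (MAD of first differences). A spot passes the
#' single-fluorophore check iff exactly one downward step is found.
#'
#' @param trace An \code{intensity_trace} of length >= 10.
#' @param penalty Split acceptance threshold in units of the noise
#'   variance (default 10).
#' @param min_seg Minimum segment length, frames (default 2).
#' @return List: \code{n_steps} (downward level changes),
#'   \code{step_frames} (frame index of the first point after each drop),
#'   \code{levels} (segment means), \code{single_fluorophore}.
#' @export
detect_bleach_steps <- function(trace, penalty = 10, min_seg = 2L) {
  stopifnot(inherits(trace, "intensity_trace"))
  y <- trace$values
  n <- length(y)
  if (n < 10L) stop("trace too short for step detection (need >= 10)",
                    call. = FALSE)
  noise_var <- (stats::mad(diff(y)) / sqrt(2))^2
  if (noise_var == 0) noise_var <- 1e-12
  boundaries <- integer(0)  # last index of each accepted left segment
  split_seg <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_seg) return()
    seg <- y[lo:hi]
    cs <- cumsum(seg); css <- cumsum(seg^2)
    tot <- css[len] - cs[len]^2 / len
    ks <- min_seg:(len - min_seg)
    rss_l <- css[ks] - cs[ks]^2 / ks
    nr <- len - ks
    rss_r <- (css[len] - css[ks]) - (cs[len] - cs[ks])^2 / nr
    red <- tot - (rss_l + rss_r)
    kbest <- ks[which.max(red)]
    if (max(red) > penalty * noise_var) {
      boundaries <<- c(boundaries, lo + kbest - 1L)
      split_seg(lo, lo + kbest - 1L)
      split_seg(lo + kbest, hi)
    }
  }
  split_seg(1L, n)
  boundaries <- sort(boundaries)
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  levels <- mapply(function(s, e) mean(y[s:e]), starts, ends)
  drops <- which(diff(levels) < 0)
  list(n_steps = length(drops),
       step_frames = trace$frames[starts[drops + 1L]],
       levels = levels,
       single_fluorophore = length(drops) == 1L)
}

#' Fit a lognormal model to a spot-intensity distribution
#'
#' Maximum-likelihood lognormal parameters (mean and sd of log intensity,
#' MLE normalization 1/n) plus a one-sample Kolmogorov-Smirnov distance
#' between the sample and the fitted lognormal as goodness of fit.
#'
#' @param intensities Positive counts, length >= 20.
#' @return List: \code{mu}, \code{sigma} (log scale), \code{gof_stat}
#'   (KS distance to the fitted lognormal).
#' @export
fit_lognormal_intensity <- function(intensities) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intensities must be positive and finite", call. = FALSE)
  n <- length(x)
  if (n < 20L) stop("need at least 20 intensities", call. = FALSE)
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  gof <- if (sigma == 0) 0 else
    suppressWarnings(stats::ks.test(x, stats::plnorm,
                                    meanlog = mu, sdlog = sigma)$statistic)
  list(mu = mu, sigma = sigma, gof_stat = unname(gof))
}

#' Link per-frame localizations into trajectories (minimum-step linking)
#'
#' Frame-to-frame globally optimal assignment: detections in consecutive
#' frames are matched so that the total link distance is minimal (linear
#' sum assignment), links longer than \code{max_step} are forbidden,
#' unmatched detections open new tracks, and a track not re-found within
#' \code{max_gap} frames terminates.
#'
#' @param locs data.frame with columns \code{frame}, \code{x_um},
#'   \code{y_um} and optionally \code{intensity}.
#' @param max_step Gate distance, micrometers.
#' @param max_gap Frames a track may go undetected (default 0:
#'   consecutive-frame linking only).
#' @return List of \code{trajectory} objects, ids "t0001", ...
#' @export
link_spots <- function(locs, max_step, max_gap = 0L) {
  stopifnot(is.data.frame(locs), max_step > 0, max_gap >= 0L)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(locs)))
    stop("locs needs columns frame, x_um, y_um", call. = FALSE)
  has_int <- "intensity" %in% names(locs)
  BIG <- 1e9
  tracks <- list()   # each: list(frames, x, y, intensity, last_frame, open)
  if (nrow(locs) == 0L) return(list())
  for (f in sort(unique(locs$frame))) {
    det <- locs[locs$frame == f, , drop = FALSE]
    nd <- nrow(det)
    open_idx <- which(vapply(tracks, function(tr)
      tr$open && f - tr$last_frame <= max_gap + 1L, logical(1)))
    assigned_det <- rep(FALSE, nd)
    if (length(open_idx) > 0L && nd > 0L) {
      cost <- matrix(BIG, length(open_idx), nd)
      for (a in seq_along(open_idx)) {
        tr <- tracks[[open_idx[a]]]
        k <- length(tr$x)
        d <- sqrt((det$x_um - tr$x[k])^2 + (det$y_um - tr$y[k])^2)
        cost[a, d <= max_step] <- d[d <= max_step]
      }
      # pad to square so every row/col can stay unassigned at cost BIG
      nr <- nrow(cost); nc <- ncol(cost)
      side <- nr + nc
      pad <- matrix(BIG, side, side)
      pad[seq_len(nr), seq_len(nc)] <- cost
      pad[seq_len(nr), nc + seq_len(nr)] <- 2 * BIG  # row dummy
      pad[nr + seq_len(nc), seq_len(nc)] <- 2 * BIG  # col dummy
      pad[nr + seq_len(nc), nc + seq_len(nr)] <- 0
      sol <- solve_assignment(pad)
      for (a in seq_len(nr)) {
        j <- sol[a]
        if (j <= nc && cost[a, j] < BIG) {
          ti <- open_idx[a]
          tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
          tracks[[ti]]$x <- c(tracks[[ti]]$x, det$x_um[j])
          tracks[[ti]]$y <- c(tracks[[ti]]$y, det$y_um[j])
          if (has_int)
            tracks[[ti]]$intensity <- c(tracks[[ti]]$intensity,
                                        det$intensity[j])
          tracks[[ti]]$last_frame <- f
          assigned_det[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        frames = f, x = det$x_um[j], y = det$y_um[j],
        intensity = if (has_int) det$intensity[j] else NULL,
        last_frame = f, open = TRUE)
    }
    # retire tracks that exceeded the gap
    for (ti in seq_along(tracks))
      if (tracks[[ti]]$open && f - tracks[[ti]]$last_frame > max_gap)
        tracks[[ti]]$open <- FALSE
  }
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    trajectory(sprintf("t%04d", i), tr$frames, tr$x, tr$y,
               intensity = tr$intensity)
  })
}

#' Filter trajectories by length and artifact steps
#'
#' Keeps tracks with at least \code{min_frames} localizations and no
#' single-frame step larger than \code{artifact_step_um} (the automated
#' surrogate for manual artifact screening; every exclusion is logged with
#' its reason).
#'
#' @param trajs List of \code{trajectory} objects.
#' @param min_frames Minimum localizations per track (default 15).
#' @param artifact_step_um Maximum plausible single-frame step,
#'   micrometers (default 1.0).
#' @return List with \code{retained} (trajectories) and \code{excluded}
#'   (data.frame \code{track_id}, \code{reason} in
#'   \{"short", "artifact_step"\}).
#' @export
filter_tracks <- function(trajs, min_frames = 15L, artifact_step_um = 1.0) {
  reasons <- vapply(trajs, function(tr) {
    if (n_points(tr) < min_frames) return("short")
    if (n_points(tr) >= 2L) {
      step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
      if (any(step > artifact_step_um)) return("artifact_step")
    }
    ""
  }, character(1))
  keep <- reasons == ""
  excluded <- data.frame(
    track_id = vapply(trajs[!keep], function(tr) tr$track_id, character(1)),
    reason = reasons[!keep], stringsAsFactors = FALSE)
  list(retained = trajs[keep], excluded = excluded)
}
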