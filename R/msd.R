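# Mean square displacement analysis. For a trajectory of N_pts positions,
#   MSD(m dT) = 1/(N_pts - m) * sum_i [ (x_{i+m}-x_i)^2 + (y_{i+m}-y_i)^2 ]
# with overlapping pairs; linear in lag for free diffusion, saturating for
# confined motion.

#' Mean square displacement curve of one trajectory
#'
#' Exact evaluation of the overlapping-pair MSD formula per lag; no
#' interpolation. Requires consecutive frames.
#'
#' @param traj A \code{trajectory}.
#' @param dt Frame interval dT, seconds.
#' @param max_lag Largest lag m (frames). Default \code{floor(N_pts / 2)}
#'   (longer lags average too few pairs to be useful).
#' @return Object of class \code{msd_curve}: \code{lags} (frames),
#'   \code{msd} (um^2), \code{n_pairs}, \code{dt}.
#' @export
msd_curve <- function(traj, dt, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"), dt > 0)
  n <- n_points(traj)
  if (n < 2L) stop("MSD needs at least 2 localizations", call. = FALSE)
  if (any(diff(traj$frames) != 1L))
    stop(sprintf("track '%s' has frame gaps; MSD requires consecutive frames",
                 traj$track_id), call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(1L, n %/% 2L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n)
    stop("max_lag must lie in [1, N_pts - 1]", call. = FALSE)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(m) {
    i <- seq_len(n - m)
    mean((traj$x[i + m] - traj$x[i])^2 + (traj$y[i + m] - traj$y[i])^2)
  }, numeric(1))
  structure(list(lags = lags, msd = msd, n_pairs = n - lags, dt = dt),
            class = "msd_curve")
}

#' Diffusion coefficient from the short-lag MSD slope
#'
#' Ordinary least squares of MSD against \eqn{4 m \Delta t} over the first
#' \code{n_lags} lags; the slope is the conventional MSD-based D and the
#' intercept absorbs the localization-noise/blur offset
#' (\eqn{4\sigma^2 - 8RD\Delta t}).
#'
#' @param curve An \code{msd_curve}.
#' @param n_lags Number of initial lags to fit (default 4, >= 2).
#' @return List with \code{D_msd} (um^2/s) and \code{intercept} (um^2).
#' @export
fit_msd_linear <- function(curve, n_lags = 4L) {
  stopifnot(inherits(curve, "msd_curve"))
  n_lags <- as.integer(n_lags)
  if (n_lags < 2L) stop("n_lags must be >= 2", call. = FALSE)
  if (n_lags > length(curve$lags))
    stop("n_lags exceeds available lags", call. = FALSE)
  t4 <- 4 * curve$lags[seq_len(n_lags)] * curve$dt
  y <- curve$msd[seq_len(n_lags)]
  fit <- stats::lm.fit(cbind(1, t4), y)
  list(D_msd = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Classify a trajectory's motion as Brownian or confined
#'
#' Fits two models to the MSD curve by least squares: free diffusion
#' \eqn{MSD = 4Dt} and the saturating confined form
#' \eqn{MSD = A(1 - e^{-4Dt/A})} whose plateau A reflects the confinement
#' area. The curve is called \code{confined} only when both hold:
#' \itemize{
#'   \item the saturating fit beats the line by more than a 5% parsimony
#'     margin (\eqn{RSS_c < 0.95\,RSS_b}), and
#'   \item the saturation is actually demonstrated inside the observation
#'     window: the longest fitted lag spans at least 3 confinement times
#'     \eqn{\tau = A/(4D_c)}, i.e. the curve ends within
#'     \eqn{e^{-3} \approx 5\%} of its plateau.
#' }
#' The second condition guards against the nested saturating model
#' absorbing the correlated wiggles of genuinely Brownian single-track MSD
#' curves. All scores are returned so users can re-threshold.
#'
#' @param curve An \code{msd_curve} with at least 8 lags.
#' @return List: \code{label} ("brownian" or "confined"), \code{rss_brownian},
#'   \code{rss_confined}, \code{D_brownian}, \code{D_confined},
#'   \code{plateau} (A, um^2), \code{saturation_span} (t_max / tau).
#' @export
classify_motion <- function(curve) {
  stopifnot(inherits(curve, "msd_curve"))
  if (length(curve$lags) < 8L)
    stop("motion classification needs >= 8 lags", call. = FALSE)
  t <- curve$lags * curve$dt
  y <- curve$msd
  if (all(y == 0)) {
    return(list(label = "confined", rss_brownian = 0, rss_confined = 0,
                D_brownian = 0, D_confined = 0, plateau = 0,
                saturation_span = Inf))
  }
  # brownian: slope through origin
  D_b <- sum(4 * t * y) / sum((4 * t)^2)
  rss_b <- sum((y - 4 * D_b * t)^2)
  # confined: optimize (log A, log D)
  sat <- function(par) {
    A <- exp(par[1]); D <- exp(par[2])
    sum((y - A * (1 - exp(-4 * D * t / A)))^2)
  }
  init <- c(log(max(max(y), 1e-8)), log(max(D_b, 1e-6)))
  fit <- stats::optim(init, sat, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  A_c <- exp(fit$par[1]); D_c <- exp(fit$par[2])
  rss_c <- fit$value
  sat_span <- 4 * D_c * max(t) / A_c   # window length in confinement times
  label <- if (rss_c < 0.95 * rss_b && sat_span >= 3) "confined"
           else "brownian"
  list(label = label, rss_brownian = rss_b, rss_confined = rss_c,
       D_brownian = D_b, D_confined = D_c, plateau = A_c,
       saturation_span = sat_span)
}
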