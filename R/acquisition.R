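#' Acquisition parameters for a single-molecule recording
#'
#' Bundles the camera timing and geometry needed to interpret trajectory
#' coordinates physically: the frame interval \eqn{\Delta t} (time between
#' the starts of consecutive frames), the exposure (integration) time, the
#' pixel size, and the motion-blur coefficient \eqn{R}.
#'
#' Under continuous illumination over the full frame, \eqn{R = 1/6}; an
#' instantaneous shutter gives \eqn{R = 0}. Valid values lie in
#' \eqn{[0, 1/4]}.
#'
#' @param frame_interval Time between frame starts, seconds.
#' @param exposure Integration time per frame, seconds
#'   (\code{0 < exposure <= frame_interval}).
#' @param pixel_size Pixel size, micrometers.
#' @param blur_coefficient Dimensionless motion-blur coefficient R.
#'   Default 1/6 (continuous illumination).
#' @return An object of class \code{acq_params}.
#' @export
#' @examples
#' acq_params(frame_interval = 0.033, exposure = 0.033, pixel_size = 0.16)
acq_params <- function(frame_interval, exposure = frame_interval,
                       pixel_size = 0.16, blur_coefficient = 1 / 6) {
  stopifnot(is.numeric(frame_interval), length(frame_interval) == 1L,
            is.numeric(exposure), length(exposure) == 1L,
            is.numeric(pixel_size), length(pixel_size) == 1L)
  if (!is.finite(exposure) || exposure <= 0)
    stop("`exposure` must be positive", call. = FALSE)
  if (!is.finite(frame_interval) || frame_interval < exposure)
    stop("`frame_interval` must be >= `exposure`", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive", call. = FALSE)
  if (blur_coefficient < 0 || blur_coefficient > 0.25)
    stop("`blur_coefficient` must lie in [0, 1/4]", call. = FALSE)
  structure(
    list(frame_interval = frame_interval, exposure = exposure,
         pixel_size = pixel_size, blur_coefficient = blur_coefficient),
    class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("Acquisition parameters\n")
  cat(sprintf("  frame interval: %g s\n", x$frame_interval))
  cat(sprintf("  exposure:       %g s\n", x$exposure))
  cat(sprintf("  pixel size:     %g um\n", x$pixel_size))
  cat(sprintf("  blur R:         %g\n", x$blur_coefficient))
  invisible(x)
}

#' Motion-blur coefficient of an arbitrary shutter profile
#'
#' Computes the dimensionless blur coefficient
#' \deqn{R = \frac{1}{T}\int_0^T S(t)\,(1 - S(t))\,dt}
#' where \eqn{S(t)} is the cumulative fraction of illumination delivered by
#' time \eqn{t} within a frame of length \eqn{T}. R captures how much the
#' time-averaging of positions during a finite exposure correlates
#' consecutive observed displacements: uniform continuous illumination gives
#' \eqn{R = 1/6}; an instantaneous (delta) shutter gives \eqn{R = 0}.
#'
#' The profile need not be normalized; it is scaled internally so that
#' \eqn{S(T) = 1}. Integration uses composite Simpson quadrature on a dense
#' grid (absolute accuracy ~1e-9 for smooth profiles).
#'
#' @param shutter_profile Function of time on \code{[0, T]}, nonnegative
#'   illumination intensity. Vectorized over its argument.
#' @param T Frame length over which the profile is defined (default 1;
#'   R is invariant to the time scale).
#' @param n_grid Number of quadrature intervals (even; default 200000).
#' @return Scalar R in \code{[0, 1/4]}.
#' @export
#' @examples
#' motion_blur_coefficient(function(t) rep(1, length(t)))  # 1/6
motion_blur_coefficient <- function(shutter_profile, T = 1,
                                    n_grid = 2e5) {
  stopifnot(is.function(shutter_profile), T > 0)
  n <- as.integer(n_grid)
  if (n %% 2L == 1L) n <- n + 1L
  t <- seq(0, T, length.out = n + 1L)
  f <- shutter_profile(t)
  if (any(!is.finite(f)) || any(f < 0))
    stop("shutter profile must be nonnegative and finite", call. = FALSE)
  h <- T / n
  # cumulative illumination by trapezoid; normalize total to 1
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * h))
  total <- cum[length(cum)]
  if (total <= 0)
    stop("shutter profile is identically zero", call. = FALSE)
  S <- cum / total
  g <- S * (1 - S)
  # composite Simpson over the same grid
  w <- rep(c(4, 2), length.out = n - 1L)
  integral <- h / 3 * (g[1] + g[n + 1L] + sum(w * g[2:n]))
  integral / T
}
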