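# Maximum-likelihood diffusion estimation from displacement series under
# the blur/noise-aware displacement covariance model.
#
# For a trajectory observed with static localization noise sd sigma under
# motion blur coefficient R, the per-axis displacement vector is Gaussian
# with symmetric tridiagonal Toeplitz covariance
#   Sigma_ii     = a = 2 D dt - 2 (2 D R dt - sigma^2)
#   Sigma_i,i+1  = b = 2 D R dt - sigma^2
# and the log-likelihood (constants dropped) is
#   L = -log|Sigma| - 1/2 dx' Sigma^-1 dx - 1/2 dy' Sigma^-1 dy.
# (D, sigma^2) maximizing L are the estimates.

#' Displacement covariance model
#'
#' @param D Diffusion coefficient, um^2/s (> 0).
#' @param sigma2 Static localization noise variance, um^2 (>= 0).
#' @param dt Frame interval, seconds.
#' @param R Motion blur coefficient in [0, 1/4].
#' @param N Number of displacement steps.
#' @return Object of class \code{covariance_model}.
#' @export
covariance_model <- function(D, sigma2, dt, R = 1 / 6, N) {
  stopifnot(D > 0, sigma2 >= 0, dt > 0, R >= 0, R <= 0.25, N >= 1)
  structure(list(D = D, sigma2 = sigma2, dt = dt, R = R, N = as.integer(N)),
            class = "covariance_model")
}

# diagonal (a) and off-diagonal (b) entries of the model
cov_entries <- function(model) {
  b <- 2 * model$D * model$R * model$dt - model$sigma2
  a <- 2 * model$D * model$dt - 2 * b
  c(a = a, b = b)
}

#' Dense displacement covariance matrix
#'
#' Builds the N-by-N symmetric tridiagonal matrix with diagonal
#' \eqn{a = 2D\Delta t - 2(2DR\Delta t - \sigma^2)} and off-diagonal
#' \eqn{b = 2DR\Delta t - \sigma^2}. Intended for small N (inspection,
#' oracles); the likelihood functions never form it.
#'
#' @param model A \code{covariance_model}.
#' @return N-by-N numeric matrix, um^2 entries.
#' @export
covariance_matrix <- function(model) {
  stopifnot(inherits(model, "covariance_model"))
  ab <- cov_entries(model)
  N <- model$N
  S <- diag(ab[["a"]], N)
  if (N > 1L) {
    idx <- seq_len(N - 1L)
    S[cbind(idx, idx + 1L)] <- ab[["b"]]
    S[cbind(idx + 1L, idx)] <- ab[["b"]]
  }
  S
}

#' Exact displacement log-likelihood
#'
#' Evaluates \eqn{L = -\log|\Sigma| - \frac12 \Delta x^T \Sigma^{-1} \Delta x
#' - \frac12 \Delta y^T \Sigma^{-1} \Delta y} via the tridiagonal
#' \eqn{LDL^T} factorization in O(N), with no dense inverse. The Gaussian
#' constant \eqn{-N\log(2\pi)} is omitted (it shifts L uniformly and cannot
#' move the maximizer).
#'
#' @param disp A \code{displacement_series}.
#' @param model A \code{covariance_model} with \code{N == length(disp$dx)}.
#' @return Scalar log-likelihood.
#' @export
loglik_exact <- function(disp, model) {
  stopifnot(inherits(disp, "displacement_series"),
            inherits(model, "covariance_model"))
  if (length(disp$dx) != model$N)
    stop("displacement length does not match model N", call. = FALSE)
  ab <- cov_entries(model)
  L <- tridiag_loglik_cpp(ab[["a"]], ab[["b"]], disp$dx, disp$dy)
  if (is.na(L))
    stop(sprintf(
      "covariance not positive definite (D=%g, sigma2=%g, dt=%g, R=%g)",
      model$D, model$sigma2, model$dt, model$R), call. = FALSE)
  L
}

#' Circulant approximation to the displacement log-likelihood
#'
#' Replaces the tridiagonal Toeplitz covariance by the circulant with
#' eigenvalues \eqn{\lambda_k = a + 2b\cos(2\pi k/N)}, so the determinant
#' and quadratic forms are available through the discrete Fourier
#' transform: \eqn{\log|\Sigma| \approx \sum_k \log\lambda_k} and
#' \eqn{\Delta^T\Sigma^{-1}\Delta \approx \frac1N \sum_k
#' |F(\Delta)_k|^2/\lambda_k}. Accurate at large N; intended as the fast
#' alternative for long tracks.
#'
#' @inheritParams loglik_exact
#' @return Scalar approximate log-likelihood.
#' @export
loglik_circulant <- function(disp, model) {
  stopifnot(inherits(disp, "displacement_series"),
            inherits(model, "covariance_model"))
  N <- model$N
  if (length(disp$dx) != N)
    stop("displacement length does not match model N", call. = FALSE)
  if (N < 3L)
    stop("circulant approximation requires N >= 3", call. = FALSE)
  ab <- cov_entries(model)
  lambda <- ab[["a"]] + 2 * ab[["b"]] * cos(2 * pi * (0:(N - 1L)) / N)
  if (any(lambda <= 0))
    stop(sprintf(
      "circulant symbol not positive (D=%g, sigma2=%g): approximation invalid",
      model$D, model$sigma2), call. = FALSE)
  qx <- sum(Mod(stats::fft(disp$dx))^2 / lambda) / N
  qy <- sum(Mod(stats::fft(disp$dy))^2 / lambda) / N
  -sum(log(lambda)) - 0.5 * qx - 0.5 * qy
}

#' Covariance-based closed-form diffusion estimator (CVE)
#'
#' Moment estimator built from the mean squared displacement per step and
#' the mean lag-1 displacement product, averaged over x and y:
#' \deqn{\hat D = (\overline{\Delta^2} + 2\overline{\Delta_k\Delta_{k+1}})
#'   / (2\Delta t)}
#' \deqn{\hat\sigma^2 = R\,\overline{\Delta^2} +
#'   (2R - 1)\,\overline{\Delta_k\Delta_{k+1}}}
#' Plugging the model's expected moments (a, b) returns (D, sigma2)
#' identically. Values may be negative on noise-dominated tracks; they are
#' returned un-clipped as a diagnostic.
#'
#' @param disp A \code{displacement_series}.
#' @param acq An \code{acq_params} (supplies dt and R).
#' @return List with \code{D_cve} (um^2/s) and \code{sigma2_cve} (um^2).
#' @export
cve_estimate <- function(disp, acq) {
  stopifnot(inherits(disp, "displacement_series"), inherits(acq, "acq_params"))
  dt <- disp$dt
  R <- acq$blur_coefficient
  N <- length(disp$dx)
  m2 <- mean(c(disp$dx^2, disp$dy^2))
  cov1 <- if (N >= 2L)
    mean(c(disp$dx[-N] * disp$dx[-1], disp$dy[-N] * disp$dy[-1]))
  else 0
  list(D_cve = (m2 + 2 * cov1) / (2 * dt),
       sigma2_cve = R * m2 + (2 * R - 1) * cov1)
}

#' Per-trajectory maximum-likelihood estimate of (D, sigma)
#'
#' Maximizes the displacement log-likelihood over
#' \eqn{(\log D, s)} with \eqn{\sigma^2 = s^2} (so \eqn{\sigma^2 = 0} is
#' attainable), using multi-start L-BFGS-B: a CVE-based start plus a
#' log-spaced D grid. Bounds: D in [1e-6, 10] um^2/s, sigma^2 in
#' [0, 0.25] um^2. Ties in L below 1e-6 are broken toward smaller D.
#' Estimates pinned at the lower D bound signal noise-dominated tracks and
#' are flagged through \code{at_bound}, not dropped.
#'
#' @param disp A \code{displacement_series} with at least 5 steps.
#' @param acq An \code{acq_params} (dt, blur coefficient R).
#' @param method Likelihood evaluation: \code{"exact"} (default) or
#'   \code{"circulant"}.
#' @param n_starts Number of optimizer starts (default 5).
#' @return Object of class \code{diffusion_estimate}: fields \code{D_hat},
#'   \code{sigma_hat2}, \code{loglik}, \code{converged}, \code{qc_pass}
#'   (NA until \code{\link{sigma_qc_filter}}), \code{at_bound},
#'   \code{method}.
#' @export
fit_mle <- function(disp, acq, method = c("exact", "circulant"),
                    n_starts = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(disp, "displacement_series"), inherits(acq, "acq_params"))
  N <- length(disp$dx)
  if (N < 5L) stop("fit_mle requires at least 5 displacement steps",
                   call. = FALSE)
  dt <- disp$dt
  R <- acq$blur_coefficient
  D_lo <- 1e-6; D_hi <- 10; s_hi <- 0.5  # sigma2 <= 0.25 um^2

  cve <- cve_estimate(disp, acq)
  D0 <- min(max(cve$D_cve, 10 * D_lo), D_hi / 2)
  s0 <- sqrt(min(max(cve$sigma2_cve, 1e-8), s_hi^2 / 2))
  grid_D <- 10^seq(-2.5, 0, length.out = max(n_starts - 1L, 1L))
  starts <- rbind(c(log(D0), s0),
                  cbind(log(grid_D), rep(0.03, length(grid_D))))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]

  if (method == "exact") {
    res <- fit_mle_exact_cpp(disp$dx, disp$dy, dt, R, starts,
                             log(D_lo), log(D_hi), s_hi,
                             500L, 1e-10)
    if (res[5] == 0) {
      return(structure(list(D_hat = NA_real_, sigma_hat2 = NA_real_,
                            loglik = NA_real_, converged = FALSE,
                            qc_pass = NA, at_bound = NA, method = method),
                       class = "diffusion_estimate"))
    }
    D_hat <- exp(res[1])
    return(structure(list(D_hat = D_hat,
                          sigma_hat2 = min(abs(res[2]), s_hi)^2,
                          loglik = res[3], converged = res[4] > 0,
                          qc_pass = NA,
                          at_bound = D_hat <= D_lo * (1 + 1e-6),
                          method = method),
                     class = "diffusion_estimate"))
  }

  # circulant path: FFT magnitudes precomputed once per track
  lambda_k <- cos(2 * pi * (0:(N - 1L)) / N)
  fx <- Mod(stats::fft(disp$dx))^2
  fy <- Mod(stats::fft(disp$dy))^2
  negll <- function(par) {
    D <- exp(min(max(par[1], log(D_lo)), log(D_hi)))
    sigma2 <- min(abs(par[2]), s_hi)^2
    b <- 2 * D * R * dt - sigma2
    a <- 2 * D * dt - 2 * b
    lam <- a + 2 * b * lambda_k
    if (any(lam <= 0)) return(1e12)
    -(-sum(log(lam)) - 0.5 * (sum(fx / lam) + sum(fy / lam)) / N)
  }
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], negll, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    fit$par[1] <- min(max(fit$par[1], log(D_lo)), log(D_hi))
    any_conv <- any_conv || fit$convergence == 0L
    if (is.null(best) ||
        fit$value < best$value - 1e-6 ||
        (abs(fit$value - best$value) <= 1e-6 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(D_hat = NA_real_, sigma_hat2 = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          qc_pass = NA, at_bound = NA, method = method),
                     class = "diffusion_estimate"))
  }
  D_hat <- exp(best$par[1])
  structure(list(D_hat = D_hat,
                 sigma_hat2 = min(abs(best$par[2]), s_hi)^2,
                 loglik = -best$value, converged = any_conv,
                 qc_pass = NA,
                 at_bound = D_hat <= D_lo * (1 + 1e-6),
                 method = method),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Diffusion estimate (%s): D = %.5g um^2/s, sigma = %.4g um, L = %.4f%s\n",
              x$method, x$D_hat, sqrt(x$sigma_hat2), x$loglik,
              if (isTRUE(x$at_bound)) " [at lower D bound]" else ""))
  invisible(x)
}

#' Fit the diffusion MLE to every trajectory in a set
#'
#' @param trajs List of \code{trajectory} objects (consecutive frames).
#' @param acq An \code{acq_params}.
#' @param method \code{"exact"} or \code{"circulant"}.
#' @return data.frame with one row per track: \code{track_id},
#'   \code{D_um2_s}, \code{sigma2_um2}, \code{loglik}, \code{converged},
#'   \code{qc_pass}, \code{at_bound}, \code{method}.
#' @export
fit_mle_tracks <- function(trajs, acq, method = c("exact", "circulant")) {
  method <- match.arg(method)
  ests <- lapply(trajs, function(tr)
    fit_mle(displacements(tr, acq$frame_interval), acq, method))
  data.frame(
    track_id = vapply(trajs, function(tr) tr$track_id, character(1)),
    D_um2_s = vapply(ests, `[[`, numeric(1), "D_hat"),
    sigma2_um2 = vapply(ests, `[[`, numeric(1), "sigma_hat2"),
    loglik = vapply(ests, `[[`, numeric(1), "loglik"),
    converged = vapply(ests, `[[`, logical(1), "converged"),
    qc_pass = NA,
    at_bound = vapply(ests, function(e) isTRUE(e$at_bound), logical(1)),
    method = method,
    stringsAsFactors = FALSE)
}

#' Quality-control filter on the estimated localization noise
#'
#' An optimization is considered inaccurate — and its trajectory excluded —
#' when the estimated static localization noise sd lies outside ±90% of the
#' group's mean: with \eqn{\mu_\sigma} the mean of \eqn{\hat\sigma} over
#' converged estimates, an estimate is retained iff
#' \eqn{\hat\sigma \in [0.1\mu_\sigma, 1.9\mu_\sigma]}. The band is
#' computed in a single pass (the mean is not recomputed after exclusion).
#'
#' @param estimates data.frame as returned by \code{\link{fit_mle_tracks}}
#'   (needs \code{sigma2_um2} and \code{converged}); at least 2 rows.
#' @return List with \code{retained} and \code{excluded} data.frames (each
#'   with \code{qc_pass} filled in) and \code{group_mean_sigma} (um).
#' @export
sigma_qc_filter <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 2L)
  sigma <- sqrt(estimates$sigma2_um2)
  use <- estimates$converged & is.finite(sigma)
  mu <- mean(sigma[use])
  pass <- use & sigma >= 0.1 * mu & sigma <= 1.9 * mu
  estimates$qc_pass <- pass
  if (!any(pass))
    warning("sigma QC excluded every estimate", call. = FALSE)
  list(retained = estimates[pass, , drop = FALSE],
       excluded = estimates[!pass, , drop = FALSE],
       group_mean_sigma = mu)
}
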