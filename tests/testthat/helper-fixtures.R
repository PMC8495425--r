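# Shared fixtures for the suite: the standard video-rate acquisition and a
# dense-matrix likelihood oracle kept deliberately independent of the
# package's tridiagonal/circulant evaluation paths.

acq33 <- acq_params(frame_interval = 0.033, exposure = 0.033,
                    pixel_size = 0.16)

# brute-force likelihood: explicit determinant and dense solve
dense_loglik <- function(disp, model) {
  S <- covariance_matrix(model)
  as.numeric(-determinant(S, logarithm = TRUE)$modulus -
               0.5 * crossprod(disp$dx, solve(S, disp$dx)) -
               0.5 * crossprod(disp$dy, solve(S, disp$dy)))
}

# brute-force minimal-cost assignment by permutation enumeration
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# independent point-in-polygon oracle: ray casting toward +x with the
# crossing-number rule, boundary handled by explicit on-segment tests
pip_oracle <- function(px, py, v, tol = 1e-9) {
  nv <- nrow(v)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    for (k in seq_len(nv)) {
      k2 <- if (k == nv) 1L else k + 1L
      a <- v[k, ]; b <- v[k2, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 > 0) max(0, min(1, sum((c(x, y) - a) * ab) / len2)) else 0
      if (sum((c(x, y) - (a + t * ab))^2) <= tol^2) return(TRUE)
    }
    crossings <- 0L
    for (k in seq_len(nv)) {
      k2 <- if (k == nv) 1L else k + 1L
      y1 <- v[k, 2]; y2 <- v[k2, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- v[k, 1] + (y - y1) / (y2 - y1) * (v[k2, 1] - v[k, 1])
        if (xint > x) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}
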