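test_that("covariance matrix entries follow the model formula", {
  m <- covariance_model(D = 0.05, sigma2 = 0.0009, dt = 0.033, R = 1 / 6,
                        N = 4)
  S <- covariance_matrix(m)
  expect_equal(S[1, 1], 0.00400, tolerance = 1e-12)
  expect_equal(S[1, 2], -0.00035, tolerance = 1e-12)
  expect_equal(S[1, 3], 0)
  expect_true(isSymmetric(S))

  m0 <- covariance_model(0.05, 0, 0.033, R = 0, N = 3)
  S0 <- covariance_matrix(m0)
  expect_equal(S0, diag(2 * 0.05 * 0.033, 3))  # independent increments

  m6 <- covariance_model(0.05, 0, 0.033, R = 1 / 6, N = 2)
  S6 <- covariance_matrix(m6)
  expect_equal(S6[1, 1], 0.00220, tolerance = 1e-12)
  expect_equal(S6[1, 2], 0.00055, tolerance = 1e-12)
})

test_that("exact likelihood agrees with the dense brute-force oracle", {
  # N = 1 with unit variance and zero displacements: L = -log 1 - 0 - 0
  d1 <- displacement_series(0, 0, dt = 1)
  expect_equal(loglik_exact(d1, covariance_model(0.5, 0, 1, R = 0, N = 1)), 0)

  set.seed(42)
  for (N in c(2, 3, 5, 10)) {
    d <- displacement_series(rnorm(N, 0, 0.06), rnorm(N, 0, 0.06), 0.033)
    m <- covariance_model(runif(1, 0.02, 0.2), runif(1, 0, 0.002),
                          0.033, 1 / 6, N)
    Le <- loglik_exact(d, m)
    Ld <- dense_loglik(d, m)
    expect_equal(Le, Ld, tolerance = 1e-10)
  }
})

test_that("quadratic terms scale with displacement magnitude", {
  set.seed(3)
  N <- 6
  d <- displacement_series(rnorm(N, 0, 0.05), rnorm(N, 0, 0.05), 0.033)
  m <- covariance_model(0.05, 0.0009, 0.033, 1 / 6, N)
  S <- covariance_matrix(m)
  ld <- as.numeric(determinant(S)$modulus)
  q <- 0.5 * (crossprod(d$dx, solve(S, d$dx)) +
                crossprod(d$dy, solve(S, d$dy)))
  d2 <- displacement_series(2 * d$dx, 2 * d$dy, 0.033)
  expect_equal(loglik_exact(d2, m), as.numeric(-ld - 4 * q),
               tolerance = 1e-10)
})

test_that("non-positive-definite parameters raise a named error", {
  d <- displacement_series(c(0.1, -0.1), c(0.1, -0.1), 0.033)
  bad <- structure(list(D = 0.05, sigma2 = 0, dt = 0.033, R = 0.6, N = 2L),
                   class = "covariance_model")  # R beyond the valid range
  expect_error(loglik_exact(d, bad), "positive definite")
})

test_that("circulant approximation converges to the exact likelihood", {
  set.seed(9)
  # exactly diagonal when b = 0 (sigma2 = 2 D R dt)
  N <- 8
  D <- 0.05; dt <- 0.033
  m_diag <- covariance_model(D, 2 * D * dt / 6, dt, 1 / 6, N)
  d <- displacement_series(rnorm(N, 0, 0.05), rnorm(N, 0, 0.05), dt)
  expect_equal(loglik_circulant(d, m_diag), loglik_exact(d, m_diag),
               tolerance = 1e-10)

  sim <- simulate_trajectory(motion_model("brownian", 0.1), acq33,
                             n_frames = 513, sigma_loc = 0.03, seed = 12)
  dl <- displacements(sim$observed, 0.033)
  ml <- covariance_model(0.1, 0.0009, 0.033, 1 / 6, 512)
  expect_lt(abs(loglik_circulant(dl, ml) - loglik_exact(dl, ml)) /
              abs(loglik_exact(dl, ml)), 0.01)

  # small N with strong off-diagonal: approximation error finite
  d4 <- displacement_series(c(0.05, -0.04, 0.03, -0.05),
                            c(0.02, 0.03, -0.04, 0.01), dt)
  m4 <- covariance_model(0.02, 0.004, dt, 1 / 6, 4)
  expect_true(is.finite(loglik_circulant(d4, m4)))
  expect_true(is.finite(loglik_exact(d4, m4)))
})

test_that("positive definiteness holds across the valid parameter range", {
  set.seed(5)
  for (i in 1:25) {
    D <- 10^runif(1, -3, 0.5); s2 <- runif(1, 0, 0.01)
    N <- sample(2:40, 1)
    d <- displacement_series(rnorm(N, 0, 0.05), rnorm(N, 0, 0.05), 0.033)
    m <- covariance_model(D, s2, 0.033, 1 / 6, N)
    expect_true(is.finite(loglik_exact(d, m)))
  }
})

test_that("CVE inverts the model moments and matches hand values", {
  # algebra: plugging the expected moments (a, b) returns (D, sigma2)
  for (prm in list(c(0.05, 0.0009), c(0.2, 0), c(0.02, 0.0025))) {
    m <- covariance_model(prm[1], prm[2], 0.033, 1 / 6, 2)
    S <- covariance_matrix(m)
    a <- S[1, 1]; b <- S[1, 2]
    expect_equal((a + 2 * b) / (2 * 0.033), prm[1], tolerance = 1e-12)
    expect_equal(a / 6 + (2 / 6 - 1) * b, prm[2], tolerance = 1e-12)
  }
  # alternating steps: noise-dominated signature with negative D
  dalt <- 0.04
  d <- displacement_series(rep(c(dalt, -dalt), 2), rep(c(dalt, -dalt), 2),
                           0.033)
  cve <- cve_estimate(d, acq33)
  expect_equal(cve$D_cve, -dalt^2 / (2 * 0.033), tolerance = 1e-12)
  z <- cve_estimate(displacement_series(rep(0, 5), rep(0, 5), 0.033), acq33)
  expect_equal(z$D_cve, 0)
  expect_equal(z$sigma2_cve, 0)
})

test_that("MLE recovers (D, sigma) on a long track and an ensemble", {
  sim <- simulate_trajectory(motion_model("brownian", 0.1), acq33,
                             n_frames = 10001, sigma_loc = 0.03, seed = 21)
  d <- displacements(sim$observed, 0.033)
  est <- fit_mle(d, acq33)
  expect_true(est$converged)
  expect_equal(est$D_hat, 0.1, tolerance = 0.05)
  expect_equal(sqrt(est$sigma_hat2), 0.03, tolerance = 0.10)

  trs <- simulate_ensemble(200, motion_model("brownian", 0.05), acq33,
                           n_frames = 30, sigma_loc = 0.03, seed = 77)
  df <- fit_mle_tracks(trs, acq33)
  expect_true(all(df$converged))
  expect_equal(mean(df$D_um2_s), 0.05, tolerance = 0.10)
})

test_that("exact and circulant fits agree on long tracks", {
  sim <- simulate_trajectory(motion_model("brownian", 0.08), acq33,
                             n_frames = 2001, sigma_loc = 0.03, seed = 4)
  d <- displacements(sim$observed, 0.033)
  e1 <- fit_mle(d, acq33, method = "exact")
  e2 <- fit_mle(d, acq33, method = "circulant")
  expect_equal(e2$D_hat, e1$D_hat, tolerance = 0.02)
})

test_that("noise-dominated alternating displacements pin D at the bound", {
  dalt <- 0.05
  d <- displacement_series(rep(c(dalt, -dalt), 10), rep(c(dalt, -dalt), 10),
                           0.033)
  est <- fit_mle(d, acq33)
  expect_true(est$converged)
  expect_true(est$at_bound)
  # at D -> 0 the alternating vector is the top eigenmode of the noise
  # covariance sigma^2 tridiag(2,-1): the sigma MLE lands near d/2, below
  # the CVE-style d/sqrt(2) scale
  expect_gt(sqrt(est$sigma_hat2), 0.9 * dalt / 2)
  expect_lt(sqrt(est$sigma_hat2), 1.1 * dalt / sqrt(2))
})

test_that("with sigma fixed at zero the MLE reduces to the moment estimator", {
  set.seed(8)
  acq0 <- acq_params(0.033, pixel_size = 0.16, blur_coefficient = 0)
  sim <- simulate_trajectory(motion_model("brownian", 0.07), acq0,
                             n_frames = 400, n_substeps = 1,
                             sigma_loc = 0, seed = 15)
  d <- displacements(sim$observed, 0.033)
  prof <- function(D) loglik_exact(d, covariance_model(D, 0, 0.033, 0,
                                                       length(d$dx)))
  D_hat <- optimize(prof, c(1e-4, 1), maximum = TRUE, tol = 1e-10)$maximum
  D_mom <- mean(c(d$dx^2, d$dy^2)) / (2 * 0.033)
  expect_equal(D_hat, D_mom, tolerance = 1e-6)
})

test_that("ensemble-mean bias shrinks as tracks lengthen", {
  D <- 0.05
  bias <- vapply(c(30, 100, 1000), function(nf) {
    trs <- simulate_ensemble(120, motion_model("brownian", D), acq33,
                             n_frames = nf, n_substeps = 10,
                             sigma_loc = 0.03, seed = 1000 + nf)
    abs(mean(fit_mle_tracks(trs, acq33)$D_um2_s) - D) / D
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 0.01)
  expect_lt(bias[3], 0.05)
})

test_that("sigma QC retains estimates within 90% of the group mean", {
  mk <- function(sig_nm) data.frame(
    track_id = sprintf("t%d", seq_along(sig_nm)),
    D_um2_s = 0.05, sigma2_um2 = (sig_nm / 1000)^2, loglik = 0,
    converged = TRUE, qc_pass = NA, at_bound = FALSE, method = "exact",
    stringsAsFactors = FALSE)
  r <- sigma_qc_filter(mk(c(30, 30, 30, 1)))
  expect_equal(nrow(r$retained), 3)
  expect_equal(r$excluded$track_id, "t4")
  expect_equal(r$group_mean_sigma * 1000, 22.75)

  r2 <- sigma_qc_filter(mk(c(25, 25, 25)))
  expect_equal(nrow(r2$retained), 3)

  r3 <- sigma_qc_filter(mk(c(10, 100)))   # mean 55, band [5.5, 104.5]
  expect_equal(nrow(r3$retained), 2)
})
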