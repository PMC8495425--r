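render_static_spots <- function(centers_um, counts = 1e4, background = 10,
                                shape = c(32, 32), n_frames = 1) {
  cam <- camera_model(psf_sigma = 0.2, counts_per_molecule = counts,
                      background = background, read_noise_sd = 0,
                      image_shape = shape, shot_noise = FALSE)
  paths <- lapply(seq_len(nrow(centers_um)), function(i)
    matrix(rep(centers_um[i, ], each = n_frames), ncol = 2))
  render_movie(paths, cam, acq33, n_frames = n_frames)
}

test_that("movie rendering honors background and peak placement", {
  cam <- camera_model(0.2, 0, background = 7, image_shape = c(16, 16),
                      shot_noise = FALSE)
  mv <- render_movie(list(), cam, acq33, n_frames = 3)
  expect_true(all(vapply(mv, function(fr) all(fr == 7), logical(1))))

  fr <- render_static_spots(rbind(c(1.6, 0.8)))[[1]]  # pixel (10, 5)
  pk <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(5 + 1, 10 + 1))
})

test_that("spot detection finds isolated spots and merges close ones", {
  expect_equal(nrow(detect_spots(matrix(5, 32, 32))), 0)

  centers <- rbind(c(1.6, 1.6), c(3.2, 1.6), c(1.6, 3.84))
  fr <- render_static_spots(centers)[[1]]
  cand <- detect_spots(fr, min_snr = 5)
  expect_equal(nrow(cand), 3)
  got <- cand[order(cand$x_px, cand$y_px), ]
  want <- round(centers / 0.16)
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(got$x_px, want[, 1])
  expect_equal(got$y_px, want[, 2])

  close2 <- render_static_spots(rbind(c(1.6, 1.6), c(1.76, 1.6)))[[1]]
  expect_equal(nrow(detect_spots(close2, min_snr = 5, window = 7)), 1)
})

test_that("2D Gaussian fitting is subpixel accurate on noiseless renders", {
  px <- 0.16
  fr <- render_static_spots(rbind(c(12.30 * px, 7.70 * px)))[[1]]
  patch <- fr[(8 - 3):(8 + 3) + 1, (12 - 3):(12 + 3) + 1]
  loc <- fit_gaussian_2d(patch, c(12, 8), px)
  expect_true(loc$fit_ok)
  expect_equal(loc$x_um / px, 12.30, tolerance = 0.01 / 12.30)
  expect_equal(loc$y_um / px, 7.70, tolerance = 0.01 / 7.70)

  # spot exactly at a pixel center: symmetric residuals pin the center
  fr2 <- render_static_spots(rbind(c(10 * px, 9 * px)))[[1]]
  patch2 <- fr2[(9 - 3):(9 + 3) + 1, (10 - 3):(10 + 3) + 1]
  loc2 <- fit_gaussian_2d(patch2, c(10, 9), px)
  expect_equal(loc2$x_um / px, 10, tolerance = 1e-6)
  expect_equal(loc2$y_um / px, 9, tolerance = 1e-6)

  flat <- fit_gaussian_2d(matrix(3, 7, 7), c(10, 10), px)
  expect_false(flat$fit_ok)
  expect_error(fit_gaussian_2d(matrix(NA_real_, 7, 7), c(1, 1), px),
               "finite")
})

test_that("localization error shrinks with photon count under shot noise", {
  px <- 0.16
  true_px <- c(12.3, 7.7)
  rmse <- vapply(c(500, 2000, 10000), function(counts) {
    errs <- vapply(1:40, function(i) {
      cam <- camera_model(0.2, counts, background = 5, read_noise_sd = 0,
                          image_shape = c(32, 32), shot_noise = TRUE)
      mv <- render_movie(list(matrix(true_px * px, ncol = 2)), cam, acq33,
                         n_frames = 1, seed = 5000 + i * 7 + counts)
      loc <- localize_movie(mv, acq33, min_snr = 4)
      if (nrow(loc) != 1) return(NA_real_)
      sqrt((loc$x_um / px - true_px[1])^2 + (loc$y_um / px - true_px[2])^2)
    }, numeric(1))
    sqrt(mean(errs^2, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 0.05)
})

test_that("intensity traces reproduce programmed levels", {
  zero <- lapply(1:5, function(i) matrix(0, 16, 16))
  tr <- trajectory("z", 0:4, rep(1.0, 5), rep(1.0, 5))
  expect_true(all(extract_intensity_trace(zero, tr, 3, 0.16)$values == 0))

  mv <- render_static_spots(rbind(c(1.6, 1.6)), counts = 5000,
                            background = 4, n_frames = 6)
  tr2 <- trajectory("s", 0:5, rep(1.6, 6), rep(1.6, 6))
  trace <- extract_intensity_trace(mv, tr2, 4, 0.16)
  expect_equal(max(trace$values) / min(trace$values), 1, tolerance = 1e-9)
  expect_equal(mean(trace$values), 5000, tolerance = 0.05)
  expect_error(extract_intensity_trace(mv, trajectory("x", 5:10,
                                                      rep(1, 6), rep(1, 6)),
                                       3, 0.16), "beyond")
})

test_that("bleach-step detection counts programmed steps", {
  flat <- intensity_trace(rep(100, 50))
  expect_equal(detect_bleach_steps(flat)$n_steps, 0)

  one <- simulate_bleach_trace(1, level = 900, bleach_frames = 24,
                               noise_sd = 20, n_frames = 60, seed = 2)
  r1 <- detect_bleach_steps(one)
  expect_equal(r1$n_steps, 1)
  expect_true(r1$single_fluorophore)
  expect_lte(abs(r1$step_frames - 24), 1)

  two <- simulate_bleach_trace(2, level = 700, bleach_frames = c(18, 40),
                               noise_sd = 20, n_frames = 70, seed = 3)
  r2 <- detect_bleach_steps(two)
  expect_equal(r2$n_steps, 2)
  expect_false(r2$single_fluorophore)
})

test_that("lognormal intensity fit is consistent and flags mixtures", {
  set.seed(6)
  x <- rlnorm(1e4, meanlog = 5, sdlog = 0.4)
  f <- fit_lognormal_intensity(x)
  expect_equal(f$mu, 5, tolerance = 0.02 / 5)
  expect_equal(f$sigma, 0.4, tolerance = 0.02 / 0.4)

  cc <- fit_lognormal_intensity(rep(42, 25))
  expect_equal(cc$mu, log(42))
  expect_equal(cc$sigma, 0)
  expect_equal(cc$gof_stat, 0)

  mix <- c(rlnorm(5000, 4, 0.2), rlnorm(5000, 6.5, 0.2))
  single <- rlnorm(10000, 5, 0.4)
  expect_gt(fit_lognormal_intensity(mix)$gof_stat,
            fit_lognormal_intensity(single)$gof_stat)
  expect_error(fit_lognormal_intensity(c(rep(1, 30), 0)), "positive")
})

test_that("assignment solver matches exhaustive enumeration", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    sol <- solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), sol)]),
                 brute_assignment(cost)$cost, tolerance = 1e-12)
  }
})

test_that("linking picks the global non-crossing optimum", {
  locs <- data.frame(frame = c(0, 0, 1, 1),
                     x_um = c(0, 10, 1, 9), y_um = c(0, 0, 0, 0))
  trs <- link_spots(locs, max_step = 2)
  expect_length(trs, 2)
  ends <- vapply(trs, function(tr) tr$x[2], numeric(1))
  starts <- vapply(trs, function(tr) tr$x[1], numeric(1))
  expect_equal(sort(abs(ends - starts)), c(1, 1))  # A->1, B->9, cost 2

  # single detection per frame: one long track
  locs2 <- data.frame(frame = 0:19, x_um = 0.01 * (0:19), y_um = 0)
  t2 <- link_spots(locs2, max_step = 1)
  expect_length(t2, 1)
  expect_equal(n_points(t2[[1]]), 20)

  # gap beyond max_gap terminates the track
  locs3 <- data.frame(frame = c(0:4, 6:9), x_um = 0, y_um = 0)
  t3 <- link_spots(locs3, max_step = 1, max_gap = 0)
  expect_length(t3, 2)
  t3g <- link_spots(locs3, max_step = 1, max_gap = 1)
  expect_length(t3g, 1)
})

test_that("linking partitions the localizations", {
  set.seed(12)
  locs <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, x_um = runif(6, 0, 5), y_um = runif(6, 0, 5))))
  trs <- link_spots(locs, max_step = 0.8)
  expect_equal(sum(vapply(trs, n_points, integer(1))), nrow(locs))
  key <- unlist(lapply(trs, function(tr) paste(tr$frames, tr$x, tr$y)))
  expect_false(anyDuplicated(key) > 0)
})

test_that("well-separated simulated tracks are recovered identically", {
  set.seed(13)
  starts <- rbind(c(1, 1), c(4, 1), c(1, 4), c(4, 4))
  sims <- lapply(seq_len(nrow(starts)), function(i)
    simulate_trajectory(motion_model("brownian", 0.05,
                                     start = starts[i, ]), acq33,
                        n_frames = 20, sigma_loc = 0.02,
                        seed = 600 + i)$observed)
  locs <- do.call(rbind, lapply(sims, function(tr)
    data.frame(frame = tr$frames, x_um = tr$x, y_um = tr$y)))
  locs <- locs[order(locs$frame), ]
  trs <- link_spots(locs, max_step = 0.5)
  expect_length(trs, 4)
  got <- lapply(trs, function(tr) round(sort(tr$x), 9))
  want <- lapply(sims, function(tr) round(sort(tr$x), 9))
  for (w in want)
    expect_true(any(vapply(got, identical, logical(1), w)))
})

test_that("track filtering applies the 15-frame and artifact rules", {
  mk <- function(id, n) trajectory(id, 0:(n - 1), 0.01 * (0:(n - 1)),
                                   rep(0, n))
  trs <- list(mk("a", 10), mk("b", 14), mk("c", 15), mk("d", 20))
  r <- filter_tracks(trs)
  expect_length(r$retained, 2)
  expect_equal(r$excluded$reason, c("short", "short"))

  r_all <- filter_tracks(trs, min_frames = 1)
  expect_length(r_all$retained, 4)

  jump <- trajectory("j", 0:29, c(0.01 * (0:14), 5 + 0.01 * (15:29)),
                     rep(0, 30))
  rj <- filter_tracks(list(jump))
  expect_length(rj$retained, 0)
  expect_equal(rj$excluded$reason, "artifact_step")
})
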