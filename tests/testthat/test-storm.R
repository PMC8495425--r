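cloud_xyz <- function(xyz, channel = "1") {
  storm_cloud(xyz, photons = rep(1000, nrow(xyz)),
              channel = rep(channel, nrow(xyz)))
}

test_that("localization filters apply the z band and photon threshold", {
  cl <- storm_cloud(cbind(1:4, 1:4, c(-400, -100, 250, 350)),
                    photons = rep(1000, 4))
  f <- filter_localizations(cl)
  expect_equal(nrow(f$points), 2)
  expect_equal(f$points[, 3], c(-100, 250))

  ident <- filter_localizations(cloud_xyz(cbind(1:3, 1:3, c(-300, 0, 300))),
                                min_photons = 0)
  expect_equal(nrow(ident$points), 3)  # closed interval keeps the edges

  ph <- storm_cloud(cbind(1:3, 1:3, 0), photons = c(50, 500, 5000))
  expect_equal(nrow(filter_localizations(ph, min_photons = 400)$points), 2)
})

test_that("DBSCAN molecule calling matches hand-worked fixtures", {
  tri <- dbscan_molecules(cloud_xyz(rbind(c(0, 0, 0), c(50, 0, 0),
                                          c(0, 50, 0))))
  expect_equal(nrow(tri$molecules), 1)
  expect_equal(tri$molecules$n_members, 3)
  expect_equal(c(tri$molecules$x_nm, tri$molecules$y_nm,
                 tri$molecules$z_nm),
               c(50 / 3, 50 / 3, 0), tolerance = 1e-12)

  two <- dbscan_molecules(cloud_xyz(rbind(c(0, 0, 0), c(50, 0, 0))))
  expect_equal(nrow(two$molecules), 0)
  expect_equal(two$n_noise, 2)

  # chain: only the middle point is core; ends join as border points
  chain <- dbscan_molecules(cloud_xyz(rbind(c(0, 0, 0), c(60, 0, 0),
                                            c(120, 0, 0))))
  expect_equal(nrow(chain$molecules), 1)
  expect_equal(chain$molecules$n_members, 3)
  expect_equal(chain$molecules$x_nm, 60)
})

test_that("DBSCAN is invariant to point order and rigid motion", {
  set.seed(30)
  s <- simulate_storm_cloud(6, 10, 12, field = 2000, background_pts = 40,
                            min_pts = 4, seed = 41)
  base <- dbscan_molecules(s$cloud)
  partition_of <- function(labels) {
    split(seq_along(labels), labels)[-1]  # drop noise group label "0"
  }
  perm <- sample(nrow(s$cloud$points))
  shuf <- storm_cloud(s$cloud$points[perm, ], s$cloud$photons[perm],
                      s$cloud$channel[perm])
  res_p <- dbscan_molecules(shuf)
  sets_base <- lapply(partition_of(base$labels), function(i) sort(i))
  sets_perm <- lapply(partition_of(res_p$labels),
                      function(i) sort(perm[i]))
  expect_setequal(unname(vapply(sets_base, paste, character(1),
                                collapse = ",")),
                  unname(vapply(sets_perm, paste, character(1),
                                collapse = ",")))

  th <- 0.6
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- storm_cloud(s$cloud$points %*% t(Rz) + 500, s$cloud$photons,
                     s$cloud$channel)
  res_r <- dbscan_molecules(rot)
  expect_equal(sort(table(base$labels[base$labels > 0])),
               sort(table(res_r$labels[res_r$labels > 0])),
               ignore_attr = TRUE)
  expect_equal(base$n_noise, res_r$n_noise)
})

test_that("every point is either clustered or noise; min_points monotone", {
  set.seed(31)
  s <- simulate_storm_cloud(5, 8, 20, field = 1500, background_pts = 60,
                            seed = 51)
  r <- dbscan_molecules(s$cloud)
  expect_equal(sum(r$labels > 0) + r$n_noise, nrow(s$cloud$points))
  clustered <- vapply(2:5, function(mp)
    sum(dbscan_molecules(s$cloud, min_points = mp)$labels > 0), numeric(1))
  expect_true(all(diff(clustered) <= 0))
})

test_that("well-separated simulated clusters are recovered exactly", {
  s <- simulate_storm_cloud(20, 10, 15, field = 8000, background_pts = 0,
                            min_pts = 5, min_separation = 450, seed = 61)
  r <- dbscan_molecules(s$cloud)
  expect_equal(nrow(r$molecules), 20)
  # membership recall: points sharing a true cluster share a call
  for (k in 1:20) {
    calls <- unique(r$labels[s$labels == k])
    expect_length(calls, 1)
    expect_gt(calls, 0)
  }
})

test_that("ROI counting agrees with an independent point-in-polygon oracle", {
  sq <- roi_polygon(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)),
                    label = "sq", units = "nm")
  mols <- data.frame(x_nm = c(500, 1000, 1500), y_nm = c(500, 500, 500))
  expect_equal(count_molecules_in_roi(mols, sq), 2)  # boundary counts

  set.seed(32)
  v <- rbind(c(0, 0), c(800, 200), c(1000, 1000), c(400, 700), c(-100, 900))
  poly <- roi_polygon(v, "concave", "nm")
  pts <- data.frame(x_nm = runif(100, -300, 1300),
                    y_nm = runif(100, -300, 1300))
  expect_equal(count_molecules_in_roi(pts, poly),
               sum(pip_oracle(pts$x_nm, pts$y_nm, v)))

  degen <- roi_polygon(rbind(c(0, 0), c(1, 1), c(2, 2)), "line", "nm")
  expect_error(count_molecules_in_roi(mols, degen), "degenerate")
})

test_that("two-channel molecule ratios propagate through the full chain", {
  mk <- function(n) data.frame(x_nm = runif(n, 0, 1000),
                               y_nm = runif(n, 0, 1000))
  sq <- roi_polygon(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)),
                    "roi", "nm")
  set.seed(33)
  r <- receptor_ratio(mk(12), mk(30), sq)
  expect_equal(r$ratio, 0.4)
  a <- mk(7)
  expect_equal(receptor_ratio(a, a, sq)$ratio, 1)
  expect_error(receptor_ratio(mk(5), mk(0), sq), "denominator")

  # programmed 2:1 cluster counts, zero background, through DBSCAN
  sa <- simulate_storm_cloud(20, 8, 12, field = 9000, background_pts = 0,
                             min_pts = 4, min_separation = 400,
                             channel = "gper1", seed = 71)
  sb <- simulate_storm_cloud(10, 8, 12, field = 9000, background_pts = 0,
                             min_pts = 4, min_separation = 400,
                             channel = "ampar", seed = 72)
  ma <- dbscan_molecules(sa$cloud)
  mb <- dbscan_molecules(sb$cloud)
  field_roi <- roi_polygon(rbind(c(-500, -500), c(9500, -500),
                                 c(9500, 9500), c(-500, 9500)),
                           "field", "nm")
  expect_equal(receptor_ratio(ma, mb, field_roi)$ratio, 2.0)
})
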