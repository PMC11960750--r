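test_that("bridge position density matches the closed form and its limits", {
  p <- bbmm_params(sigma2_m = 0.01, location_error_sd = 10)
  b <- bridge_position_density(c(0, 0), c(10, 20), 900, c(0, 0.5, 1), p)
  expect_equal(b$mean_x, c(0, 5, 10))
  expect_equal(b$mean_y, c(0, 10, 20))
  # alpha = 0.5: 900*0.25*0.01 + 0.5*100 = 52.25
  expect_equal(b$var[2], 52.25)
  # endpoint with zero error: point mass
  p0 <- bbmm_params(sigma2_m = 0.01, location_error_sd = 0)
  expect_equal(bridge_position_density(c(0, 0), c(10, 0), 900, 0, p0)$var, 0)
  # degenerate limit: sigma2 = 0 and delta = 0 has zero variance throughout
  pz <- bbmm_params(sigma2_m = 0, location_error_sd = 0)
  expect_equal(bridge_position_density(c(0, 0), c(10, 0), 900,
                                       seq(0, 1, 0.25), pz)$var, rep(0, 5))
  expect_error(bridge_position_density(c(0, 0), c(1, 1), 0, 0.5, p),
               "duration")
})

test_that("sigma2_m recovery and directional responses behave", {
  # stochastic parameter-recovery oracle, small-n version (full 20-track
  # median is asserted in test-acceptance.R)
  est <- vapply(1:5, function(i)
    as.numeric(estimate_brownian_variance(
      simulate_brownian_track(0.05, 200, 900, 5, seed = 100 + i),
      location_error_sd = 5)), 0)
  expect_lt(abs(median(est) / 0.05 - 1), 0.3)

  # doubling delta on the same data lowers the estimate
  trk <- simulate_brownian_track(0.05, 200, 900, 5, seed = 17)
  e1 <- as.numeric(estimate_brownian_variance(trk, 5))
  e2 <- suppressWarnings(as.numeric(estimate_brownian_variance(trk, 10)))
  expect_lt(e2, e1)

  # collinear on-schedule track with delta = 0: estimate collapses to the
  # lower bound with a warning
  lin <- make_track(seq(0, 900 * 9, 900), seq(0, 90, 10), rep(0, 10))
  expect_warning(e0 <- estimate_brownian_variance(lin, 0), "bound")
  expect_lt(as.numeric(e0), 1e-6)

  expect_error(estimate_brownian_variance(make_track(c(0, 900), 0:1, 0:1)),
               "triple")
})

test_that("bbmm occupancy conserves bridged time and matches limits", {
  g <- grid_spec(-150, -150, 15, 20, 20)
  p <- bbmm_params(sigma2_m = 0.05, location_error_sd = 5, K = 100)

  # one bridge fully inside a padded grid: total = T within 1e-3 T
  trk <- make_track(c(0, 900), c(-20, 20), c(0, 5))
  r <- bbmm_occupancy(trk, g, p)
  expect_equal(sum(r$values) + attr(r, "leakage_s"), 900, tolerance = 1e-9)
  expect_lt(abs(sum(r$values) - 900), 1e-3 * 900)

  # near-stationary, near-zero variance: all mass in the containing cell
  trk2 <- make_track(c(0, 900), c(7, 7), c(7, 7))
  pz <- bbmm_params(sigma2_m = 1e-12, location_error_sd = 1e-6)
  r2 <- bbmm_occupancy(trk2, g, pz)
  expect_equal(r2$values[locate_cell(g, 7, 7)$ix + 1,
                         locate_cell(g, 7, 7)$iy + 1], 900,
               tolerance = 1e-6)

  # gaps beyond max_bridge_gap are excluded and reported
  trk3 <- make_track(c(0, 900, 900 + 30000), c(0, 10, 20), c(0, 0, 0))
  r3 <- bbmm_occupancy(trk3, g, p)
  expect_equal(attr(r3, "bridged_s"), 900)
  expect_equal(attr(r3, "unbridged_s"), 30000)

  # refining K changes no cell by more than 1% of the raster maximum
  herd <- small_herd()
  trk4 <- head(herd$fixes[herd$fixes$animal_id == "cow01", ], 120)
  gg <- make_grid(trk4, 15, 60)
  s2 <- as.numeric(estimate_brownian_variance(trk4))
  r50 <- bbmm_occupancy(trk4, gg, bbmm_params(s2, 5, K = 50))
  r200 <- bbmm_occupancy(trk4, gg, bbmm_params(s2, 5, K = 200))
  expect_lt(max(abs(r50$values - r200$values)), 0.01 * max(r200$values))
})

test_that("activity-weighted bbmm conserves covered index mass", {
  g <- grid_spec(-300, -300, 15, 40, 40)
  p <- bbmm_params(sigma2_m = 0.05, location_error_sd = 5, K = 100)

  # single bridge exactly spanning one sample of 3000: total = 3000 +- 3
  trk <- make_track(c(0, 1800), c(-20, 20), c(0, 0))
  act <- make_activity(0, 3000)
  r <- bbmm_cumulative_activity(trk, act, g, p)
  expect_lt(abs(sum(r$values) - 3000), 3)
  expect_equal(attr(r, "covered_index"), 3000, tolerance = 1e-9)

  # zero-index sample contributes nothing
  r0 <- bbmm_cumulative_activity(trk, make_activity(0, 0), g, p)
  expect_equal(sum(r0$values), 0)

  # two equal-duration bridges inside one long sample, far apart on the
  # grid (the gap between them is not bridged): each receives half of the
  # covered index mass
  p2 <- bbmm_params(sigma2_m = 0.05, location_error_sd = 5, K = 100,
                    max_bridge_gap = 1000)
  trk2 <- make_track(c(0, 450, 20000, 20450),
                     c(-200, -200, 200, 200), c(0, 10, 0, 10))
  act2 <- make_activity(0, 3000, len = 21600)
  r2 <- bbmm_cumulative_activity(trk2, act2, g, p2)
  left <- sum(r2$values[1:20, ]); right <- sum(r2$values[21:40, ])
  expect_equal(left, right, tolerance = 1e-6)
  # covered fraction = 900 s of 21600 s
  expect_equal(left + right, 3000 * 900 / 21600, tolerance = 0.2)

  # point-mass limit reduces to the cell-count split rule
  pz <- bbmm_params(sigma2_m = 1e-12, location_error_sd = 1e-6, K = 100)
  trk3 <- make_track(c(0, 900), c(7, 52), c(7, 7))
  r3 <- bbmm_cumulative_activity(trk3, make_activity(0, 3000), g, pz)
  cc <- cumulative_activity_cellcount(trk3, make_activity(0, 3000),
                                      g)
  # same two cells hold the mass; bbmm spreads along the segment instead of
  # splitting at fixes, so compare supports not cell-wise values
  expect_equal(sum(r3$values), 3000, tolerance = 3)
  expect_equal(sum(cc$values), 3000, tolerance = 1e-9)
})

test_that("bbmm average activity is the rate ratio with an occupancy floor", {
  g <- grid_spec(0, 0, 15, 2, 1)
  occ <- ud_raster(g, matrix(c(1800, 3600), 2, 1), "seconds")
  cum <- ud_raster(g, matrix(c(3000, 3000), 2, 1), "activity counts")
  avg <- bbmm_average_activity(cum, occ)
  expect_equal(as.numeric(avg$values), c(3000, 1500))
  occ2 <- ud_raster(g, matrix(c(30, 3600), 2, 1), "seconds")
  avg2 <- bbmm_average_activity(cum, occ2, min_occupancy = 60)
  expect_true(is.na(avg2$values[1, 1]))
  g2 <- grid_spec(0, 0, 15, 3, 1)
  expect_error(bbmm_average_activity(cum, ud_raster(g2)), "grid")
})

test_that("as variances vanish bbmm converges to the straight-line raster", {
  g <- grid_spec(-15, -15, 15, 12, 4)
  trk <- make_track(c(0, 900), c(0, 150), c(0, 20))
  pz <- bbmm_params(sigma2_m = 1e-12, location_error_sd = 1e-6, K = 400)
  r <- bbmm_occupancy(trk, g, pz)
  # dense segment rasterization oracle
  tt <- seq(0.5 / 4000, 1 - 0.5 / 4000, length.out = 4000)
  seg <- true_occupancy(
    data.frame(time = trk$time[1] + tt * 900,
               x = (1 - tt) * 0 + tt * 150, y = (1 - tt) * 0 + tt * 20),
    g)
  bc <- bhattacharyya_coefficient(normalize_raster(r), normalize_raster(seg))
  expect_gt(bc, 0.99)
})
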