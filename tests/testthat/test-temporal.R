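mk_obs <- function(start_s, labels, animal_id = "a", observer = "o1") {
  data.frame(animal_id = animal_id,
             minute = as.POSIXct("2023-10-09", tz = "UTC") + start_s +
               60 * (seq_along(labels) - 1),
             label = labels, observer_id = observer, stringsAsFactors = FALSE)
}

test_that("grazing proportions respect the coverage rule", {
  act <- make_activity(c(0, 1800, 3600), c(4000, 2000, 1000))
  obs <- rbind(mk_obs(0, rep("grazing", 30)),
               mk_obs(1800, rep(c("grazing", "non_grazing"), 15)),
               mk_obs(3600, rep("non_grazing", 20)))   # 20 of 30 min only
  # align the activity intervals with the observation day
  act$interval_start <- as.POSIXct("2023-10-09", tz = "UTC") + c(0, 1800, 3600)
  gp <- grazing_proportions(obs, act)
  expect_equal(nrow(gp), 2)
  expect_equal(gp$proportion_grazing, c(1.0, 0.5))
  expect_equal(attr(gp, "excluded_periods"), 1L)
  # relaxed coverage admits the partial period, proportion over observed
  gp2 <- grazing_proportions(obs, act, min_coverage = 0.5)
  expect_equal(nrow(gp2), 3)
  expect_equal(gp2$proportion_grazing[3], 0)
  expect_equal(gp2$minutes_observed[3], 20)
})

test_that("OLS fit matches the normal equations and handles edge cases", {
  # (0,0), (1,1), (2,0): slope 0, r^2 = 0
  per <- data.frame(proportion_grazing = c(0, 1, 2),
                    activity_index = c(0, 1, 0))
  f <- fit_activity_grazing_line(per)
  expect_equal(f$slope, 0)
  expect_equal(f$r_squared, 0)

  # exact line: r^2 = 1
  per2 <- data.frame(proportion_grazing = c(0, 0.5, 1),
                     activity_index = c(600, 2600, 4600))
  f2 <- fit_activity_grazing_line(per2)
  expect_equal(f2$r_squared, 1)
  expect_equal(threshold_from_fit(f2, 0.5), 2600)
  expect_equal(threshold_from_fit(f2, 0), f2$intercept)
  expect_equal(threshold_from_fit(f2, 1), f2$intercept + f2$slope)

  # brute-force normal equations on random inputs, to 1e-10
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- runif(n); y <- 600 + 4000 * x + rnorm(n, 0, 300)
    fr <- fit_activity_grazing_line(
      data.frame(proportion_grazing = x, activity_index = y))
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fr$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fr$slope, beta[2], tolerance = 1e-10)
    # permutation invariance
    o <- sample(n)
    fp <- fit_activity_grazing_line(
      data.frame(proportion_grazing = x[o], activity_index = y[o]))
    expect_equal(fp$slope, fr$slope, tolerance = 1e-12)
  }
  expect_error(fit_activity_grazing_line(
    data.frame(proportion_grazing = c(1, 1, 1), activity_index = 1:3)),
    "constant")
})

test_that("midpoint threshold rounds half away from zero", {
  expect_identical(midpoint_threshold(1848, 2617), 2233)  # 2232.5 rounds up
  expect_identical(midpoint_threshold(0, 0), 0)
  expect_identical(midpoint_threshold(2500, 2500), 2500)
})

test_that("intensity classification partitions at the threshold", {
  act <- make_activity(c(0, 1800, 3600, 86400), c(2499, 2500, 0, 9000))
  cl <- classify_intensity(act, threshold = 2500)
  expect_equal(cl$samples$intensity, c("low", "high", "low", "high"))
  expect_equal(cl$daily$low, c(2L, 0L))
  expect_equal(cl$daily$high, c(1L, 1L))
  expect_equal(cl$daily$low + cl$daily$high,
               as.integer(table(as.Date(act$interval_start))[
                 as.character(cl$daily$day)]))
})

test_that("hourly profiles pool and split correctly", {
  act <- rbind(make_activity(c(0, 86400), c(1000, 1000), "a"),
               make_activity(c(0, 86400), c(3000, 3000), "b"))
  prof <- hourly_profile(act, "combined")
  expect_equal(prof$mean_index[prof$hour == 0], 2000)
  expect_equal(prof$n[prof$hour == 0], 4L)
  expect_true(all(is.na(prof$mean_index[prof$hour != 0])))
  pa <- hourly_profile(act, "per_animal")
  expect_equal(pa$mean_index[pa$animal_id == "a" & pa$hour == 0], 1000)
  expect_equal(pa$mean_index[pa$animal_id == "b" & pa$hour == 0], 3000)
  # timezone offset shifts the bin
  prof2 <- hourly_profile(act, "combined", tz_offset_hours = 1)
  expect_equal(prof2$n[prof2$hour == 1], 4L)
})

test_that("spearman_rho equals brute-force rank Pearson on permutations", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_rho(1:5, 5:1)$rho, -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  # all permutations of n = 4 and 5 against the rank-Pearson oracle
  for (n in 4:5) {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    x <- seq_len(n)
    for (p in perms(x)) {
      got <- spearman_rho(x, p)$rho
      want <- cor(rank(x), rank(p))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # average ranks for ties match base R's method
  x <- c(1, 2, 2, 3); y <- c(10, 20, 20, 15)
  expect_equal(spearman_rho(x, y)$rho,
               suppressWarnings(cor.test(x, y, method = "spearman")$estimate[[1]]),
               tolerance = 1e-12)
  expect_error(spearman_rho(1:4, 1:5), "length")
  expect_error(spearman_rho(rep(1, 4), 1:4), "rank variance")
})

test_that("bouts are maximal runs terminated by session gaps", {
  obs <- mk_obs(0, c("grazing", "grazing", "grazing", "non_grazing",
                     "non_grazing", "grazing"))
  b <- extract_bouts(obs)
  expect_equal(b$bouts$duration_min, c(3L, 2L, 1L))
  expect_equal(unname(b$mean_duration_s["grazing"]), 120)
  expect_equal(unname(b$mean_duration_s["non_grazing"]), 120)
  # conservation: durations per label sum to labelled minutes
  expect_equal(sum(b$bouts$duration_min[b$bouts$label == "grazing"]),
               sum(obs$label == "grazing"))

  # a session gap splits same-label runs
  obs2 <- rbind(mk_obs(0, c("grazing", "grazing")),
                mk_obs(3600, c("grazing", "grazing")))
  b2 <- extract_bouts(obs2)
  expect_equal(nrow(b2$bouts), 2)

  # single label throughout: one bout
  b3 <- extract_bouts(mk_obs(0, rep("grazing", 10)))
  expect_equal(nrow(b3$bouts), 1)
})

test_that("temperature series comparison joins hours and reports offsets", {
  t0 <- as.POSIXct("2023-10-01", tz = "UTC")
  sensor <- data.frame(animal_id = "a", time = t0 + seq(0, 86400 - 1800, 1800),
                       temp_c = 10 + sin(seq(0, 2 * pi, length.out = 48)))
  hours <- t0 + seq(0, 86400 - 3600, 3600)
  hourly_sensor <- tapply(sensor$temp_c, floor(as.numeric(sensor$time) / 3600),
                          mean)
  station_eq <- data.frame(time = hours, temp_c = as.numeric(hourly_sensor))
  r <- series_compare_temperature(sensor, station_eq)
  expect_equal(r$rho, 1)
  expect_equal(r$offset_c, 0, tolerance = 1e-12)
  station_lo <- station_eq; station_lo$temp_c <- station_lo$temp_c - 2
  r2 <- series_compare_temperature(sensor, station_lo)
  expect_equal(r2$rho, 1)
  expect_equal(r2$offset_c, 2, tolerance = 1e-12)
  station_far <- station_eq; station_far$time <- station_far$time + 4e6
  expect_error(series_compare_temperature(sensor, station_far), "overlap")
})
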