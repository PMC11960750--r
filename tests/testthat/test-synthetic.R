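test_that("herd simulation honours the schedule arithmetic and the seed", {
  herd <- small_herd()
  expect_equal(length(unique(herd$fixes$animal_id)), 3)
  # 48 activity samples per day per animal
  expect_equal(nrow(herd$activity), 3 * 7 * 48)
  expect_equal(nrow(herd$truth), 3 * 7 * 1440)
  # same seed twice: identical outputs
  again <- simulate_herd(sim_config(duration_days = 7, seed = 42))
  expect_identical(herd$fixes, again$fixes)
  expect_identical(herd$activity, again$activity)
  expect_identical(herd$truth, again$truth)
  other <- simulate_herd(sim_config(duration_days = 7, seed = 43))
  expect_false(identical(herd$activity$index, other$activity$index))
})

test_that("fix cadence is 15 min while active, 60-120 min while resting", {
  herd <- small_herd()
  trk <- herd$fixes[herd$fixes$animal_id == "cow01", ]
  truth <- herd$truth[herd$truth$animal_id == "cow01", ]
  state_at <- truth$state[match(trunc(as.numeric(trk$time) / 60),
                                trunc(as.numeric(truth$time) / 60))]
  gaps <- diff(as.numeric(trk$time)) / 60
  from_state <- state_at[-length(state_at)]
  expect_true(all(gaps[from_state != "resting"] == 15))
  expect_true(all(gaps[from_state == "resting"] >= 60 &
                    gaps[from_state == "resting"] <= 120))
})

test_that("true positions stay in the field; activity magnitudes rank by state", {
  herd <- small_herd()
  cfg <- herd$config
  expect_true(all(herd$truth$x >= cfg$field_xlim[1] &
                    herd$truth$x <= cfg$field_xlim[2]))
  expect_true(all(herd$truth$y >= cfg$field_ylim[1] &
                    herd$truth$y <= cfg$field_ylim[2]))
  expect_true(all(herd$activity$index >= 0))

  # blocks fully in one state: grazing median >> resting median
  truth <- herd$truth
  block <- paste(truth$animal_id,
                 trunc(as.numeric(truth$time) / 1800))
  pure <- tapply(truth$state, block, function(s)
    if (length(unique(s)) == 1) s[1] else NA_character_)
  key <- paste(herd$activity$animal_id,
               trunc(as.numeric(herd$activity$interval_start) / 1800))
  idx_state <- pure[key]
  gz <- herd$activity$index[idx_state == "grazing" & !is.na(idx_state)]
  rs <- herd$activity$index[idx_state == "resting" & !is.na(idx_state)]
  expect_gt(length(gz), 100)
  expect_gt(length(rs), 100)
  expect_gt(median(gz), median(rs))
  expect_gt(median(gz), 2500)   # grazing blocks sit in the high-intensity class
  expect_lt(median(rs), 2500)
})

test_that("brownian track statistics match their generating parameters", {
  trk0 <- simulate_brownian_track(0, 10, 900, 0, seed = 5)
  expect_true(all(trk0$x == trk0$x[1] & trk0$y == trk0$y[1]))
  trk <- simulate_brownian_track(0.05, 2000, 900, 0, seed = 6)
  v <- (var(diff(trk$x)) + var(diff(trk$y))) / 2 / 900
  expect_lt(abs(v / 0.05 - 1), 0.15)
  expect_identical(simulate_brownian_track(0.05, 50, 900, 5, seed = 8),
                   simulate_brownian_track(0.05, 50, 900, 5, seed = 8))
})

test_that("true occupancy conserves time and agrees with cell counts", {
  herd <- small_herd()
  grid <- make_grid(herd$fixes, 15, 30)
  tocc <- true_occupancy(herd$truth, grid)
  expect_equal(sum(tocc$values), nrow(herd$truth) * 60)
  # stationary oracle: one animal parked at a point for 1 h
  still <- data.frame(time = as.POSIXct("2023-09-29", tz = "UTC") + 60 * (0:59),
                      x = 7, y = 7)
  r <- true_occupancy(still, grid_spec(0, 0, 15, 2, 2))
  expect_equal(r$values[1, 1], 3600)
  expect_equal(sum(r$values), 3600)
  # emitted fixes reconstruct the truth well (cross-method oracle)
  cc <- occupancy_cellcount(herd$fixes, grid)
  bc <- bhattacharyya_coefficient(normalize_raster(cc),
                                  normalize_raster(tocc))
  expect_gt(bc, 0.9)
})

test_that("observation sessions cover 936 min per animal and label by state", {
  herd <- small_herd()
  obs <- simulate_observations(herd, n_days = 4, session_min = 117)
  expect_equal(sum(obs$animal_id == "cow01"), 4 * 117)
  truth <- herd$truth[herd$truth$animal_id == "cow01", ]
  o1 <- obs[obs$animal_id == "cow01", ]
  st <- truth$state[match(as.numeric(o1$minute), as.numeric(truth$time))]
  expect_identical(o1$label == "grazing", st == "grazing")
})

test_that("longer grazing dwell raises the high-intensity fraction", {
  frac_high <- function(dwell, seed) {
    h <- simulate_herd(sim_config(duration_days = 3, n_animals = 1,
                                  graze_dwell_min = dwell, seed = seed))
    mean(h$activity$index >= 2500)
  }
  # trend across seeds: grazing dwell up => more high-intensity samples
  lo <- vapply(1:5, function(s) frac_high(6, s), 0)
  hi <- vapply(1:5, function(s) frac_high(45, s), 0)
  expect_gt(mean(hi), mean(lo))
})

test_that("synthetic datasets round-trip through the text formats", {
  herd <- small_herd()
  obs <- simulate_observations(herd, n_days = 2)
  dir <- tempfile()
  write_synthetic_dataset(herd, obs, dir)
  expect_true(all(file.exists(file.path(dir,
    c("collar.csv", "observations.csv", "station.csv", "truth.csv",
      "sim_config.json")))))
  back <- read_collar_records(file.path(dir, "collar.csv"))
  expect_equal(nrow(back$fixes), nrow(herd$fixes))
  expect_equal(back$activity$index, herd$activity$index)
  obs_back <- read_observation_minutes(file.path(dir, "observations.csv"))
  expect_equal(nrow(obs_back), nrow(obs))
  expect_equal(sort(unique(obs_back$label)), sort(unique(obs$label)))
})
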