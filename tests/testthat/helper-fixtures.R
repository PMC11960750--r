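# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small herd (3 animals, 7 days) for unit-scale pipeline tests.
small_herd <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_herd(sim_config(duration_days = 7,
                                                   seed = 42))
  }
  .fixture_env$small
}

# Full default herd (3 animals, 58 days, seed 42): the acceptance world.
default_herd <- function() {
  if (is.null(.fixture_env$full)) {
    .fixture_env$full <- simulate_herd(sim_config(seed = 42))
  }
  .fixture_env$full
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Minimal projected fix track: times in seconds from an arbitrary origin.
make_track <- function(t_s, x, y, animal_id = "a") {
  data.frame(animal_id = animal_id,
             time = as.POSIXct("2023-09-29", tz = "UTC") + t_s,
             x = x, y = y, stringsAsFactors = FALSE)
}

make_activity <- function(start_s, index, animal_id = "a", len = 1800) {
  data.frame(animal_id = animal_id,
             interval_start = as.POSIXct("2023-09-29", tz = "UTC") + start_s,
             interval_length = len, index = index, stringsAsFactors = FALSE)
}

# Probability raster over a 1 x n grid from a numeric vector.
prob_vec <- function(v) {
  g <- grid_spec(0, 0, 15, length(v), 1)
  normalize_raster(ud_raster(g, matrix(v, length(v), 1)))
}

# Exhaustive greedy oracle for the volume isopleth: sort densities
# descending with lexicographic tie-break, take the shortest prefix whose
# mass reaches the level.
iso_oracle_cells <- function(p, level) {
  v <- p$values
  v[is.na(v)] <- 0
  idx <- which(v > 0, arr.ind = TRUE)
  df <- data.frame(ix = idx[, 1] - 1L, iy = idx[, 2] - 1L, d = v[idx])
  df <- df[order(-df$d, df$ix, df$iy), ]
  n <- which(cumsum(df$d) >= level - 1e-12)[1]
  df[seq_len(n), c("ix", "iy")]
}
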