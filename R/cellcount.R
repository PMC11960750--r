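# Cell-count utilization distributions: dwell time, cumulative and mean
# activity, and mean collar temperature per grid cell.

.split_animals <- function(df) split(df, df$animal_id)

# Symmetric midpoint dwell times for one sorted track: fix i is credited
# half of each adjacent inter-fix interval, each half capped at max_gap.
.dwell_times <- function(times, max_gap) {
  n <- length(times)
  if (n < 2) return(rep(0, n))
  gaps <- pmin(diff(as.numeric(times)), max_gap)
  fwd <- c(gaps, 0)
  bwd <- c(0, gaps)
  (fwd + bwd) / 2
}

#' Occupancy (dwell-time) raster by the cell-count method
#'
#' Each GPS fix is credited with half of each adjacent inter-fix interval
#' (each half capped at `max_gap` seconds, so data dropouts do not inflate
#' dwell); the credited seconds are added to the fix's grid cell when the
#' fix time falls inside `window`.  End fixes of a track carry only their
#' single available half-interval; a track with one fix contributes
#' nothing.
#'
#' @param fixes Projected, time-sorted fix data frame (`animal_id`, `time`,
#'   `x`, `y`); multiple animals are accumulated onto one raster.
#' @param grid A [grid_spec()].
#' @param window A [time_window()] (default full).
#' @param max_gap Cap on each credited half-interval's source gap, seconds
#'   (default 21600 = 6 h).
#' @return A `ud_raster` in seconds, with attributes `credited_s` (total
#'   credited time) and `oob_fixes` (count of out-of-bounds fixes skipped).
#' @export
occupancy_cellcount <- function(fixes, grid, window = time_window("full"),
                                max_gap = 21600) {
  stopifnot(max_gap > 0)
  r <- ud_raster(grid, units = "seconds")
  oob <- 0L
  for (trk in .split_animals(fixes)) {
    dwell <- .dwell_times(trk$time, max_gap)
    keep <- in_window(window, trk$time) & dwell > 0
    if (!any(keep)) next
    cell <- locate_cell(grid, trk$x[keep], trk$y[keep])
    ok <- !is.na(cell$ix)
    oob <- oob + sum(!ok)
    if (any(ok)) {
      idx <- cbind(cell$ix[ok] + 1L, cell$iy[ok] + 1L)
      w <- dwell[keep][ok]
      for (i in seq_len(nrow(idx)))
        r$values[idx[i, 1], idx[i, 2]] <- r$values[idx[i, 1], idx[i, 2]] + w[i]
    }
  }
  attr(r, "credited_s") <- sum(r$values)
  attr(r, "oob_fixes") <- oob
  r
}

# Assign each activity sample to fixes: equal split among fixes inside the
# sample interval; if none, all mass to the nearest-in-time fix within
# max_gap; otherwise dropped.  Returns per-fix (row of trk) index shares
# and share weights, plus the dropped-sample count.
.assign_activity <- function(trk, act, window, max_gap) {
  ft <- as.numeric(trk$time)
  shares <- numeric(nrow(trk))
  weights <- numeric(nrow(trk))
  dropped <- 0L
  keep <- in_window(window, act$interval_start)
  for (j in which(keep)) {
    u <- as.numeric(act$interval_start[j])
    len <- act$interval_length[j]
    inside <- which(ft >= u & ft < u + len)
    if (length(inside) > 0) {
      k <- length(inside)
      shares[inside] <- shares[inside] + act$index[j] / k
      weights[inside] <- weights[inside] + 1 / k
    } else {
      d <- pmin(abs(ft - u), abs(ft - (u + len)))
      i <- which.min(d)
      if (length(i) == 1 && d[i] <= max_gap) {
        shares[i] <- shares[i] + act$index[j]
        weights[i] <- weights[i] + 1
      } else dropped <- dropped + 1L
    }
  }
  list(shares = shares, weights = weights, dropped = dropped)
}

.accumulate_cells <- function(grid, x, y, w) {
  v <- matrix(0, grid$nx, grid$ny)
  cnt <- matrix(0, grid$nx, grid$ny)
  cell <- locate_cell(grid, x, y)
  ok <- !is.na(cell$ix) & w != 0
  oob <- sum(is.na(cell$ix) & w != 0)
  for (i in which(ok)) {
    v[cell$ix[i] + 1L, cell$iy[i] + 1L] <-
      v[cell$ix[i] + 1L, cell$iy[i] + 1L] + w[i]
    cnt[cell$ix[i] + 1L, cell$iy[i] + 1L] <-
      cnt[cell$ix[i] + 1L, cell$iy[i] + 1L] + 1
  }
  list(values = v, count = cnt, oob = oob)
}

#' Cumulative activity raster by the cell-count method
#'
#' Each 30-min activity-index sample is split equally among the fixes
#' whose timestamps fall inside its interval (generalizing "split equally
#' between consecutive locations" to 1-3 fixes per interval).  A sample
#' with no in-interval fix goes whole to the nearest-in-time fix within
#' `max_gap`, else it is dropped and counted.
#'
#' @inheritParams occupancy_cellcount
#' @param activity Activity sample data frame (`animal_id`,
#'   `interval_start`, `interval_length`, `index`).
#' @return A `ud_raster` in activity counts with attributes
#'   `assigned_index` and `dropped_samples`.
#' @export
cumulative_activity_cellcount <- function(fixes, activity, grid,
                                          window = time_window("full"),
                                          max_gap = 21600) {
  r <- ud_raster(grid, units = "activity counts")
  dropped <- 0L; oob <- 0L
  acts <- .split_animals(activity)
  for (trk in .split_animals(fixes)) {
    act <- acts[[trk$animal_id[1]]]
    if (is.null(act)) next
    a <- .assign_activity(trk, act, window, max_gap)
    dropped <- dropped + a$dropped
    acc <- .accumulate_cells(grid, trk$x, trk$y, a$shares)
    oob <- oob + acc$oob
    r$values <- r$values + acc$values
  }
  attr(r, "assigned_index") <- sum(r$values)
  attr(r, "dropped_samples") <- dropped
  attr(r, "oob_fixes") <- oob
  r
}

#' Average activity raster by the cell-count method
#'
#' Contribution-weighted mean activity index per cell: a fix that received
#' `1/k` of a sample's index carries weight `1/k`, so the cell value is
#' (sum of index shares) / (sum of share weights) and keeps the units of
#' a 30-min activity index.  Cells receiving no share are `NA` (empty,
#' distinct from an observed zero).
#'
#' @inheritParams cumulative_activity_cellcount
#' @return A `ud_raster` (mean activity index; empty cells `NA`).
#' @export
average_activity_cellcount <- function(fixes, activity, grid,
                                       window = time_window("full"),
                                       max_gap = 21600) {
  num <- matrix(0, grid$nx, grid$ny)
  den <- matrix(0, grid$nx, grid$ny)
  acts <- .split_animals(activity)
  for (trk in .split_animals(fixes)) {
    act <- acts[[trk$animal_id[1]]]
    if (is.null(act)) next
    a <- .assign_activity(trk, act, window, max_gap)
    num <- num + .accumulate_cells(grid, trk$x, trk$y, a$shares)$values
    den <- den + .accumulate_cells(grid, trk$x, trk$y, a$weights)$values
  }
  v <- num / den
  v[den == 0] <- NA_real_
  ud_raster(grid, v, units = "mean activity index")
}

#' Mean collar temperature raster
#'
#' Each temperature sample is mapped to the grid cell of the same
#' animal's nearest-in-time fix within `max_gap`; the cell value is the
#' arithmetic mean of its samples.  Cells with no sample are `NA`
#' (no-data, rendered blank on maps).
#'
#' @inheritParams occupancy_cellcount
#' @param temps Temperature data frame (`animal_id`, `time`, `temp_c`).
#' @return List with `mean` (a `ud_raster`, degC, `NA` = no data), `count`
#'   (samples per cell) and `dropped` (samples with no fix in reach).
#' @export
mean_temperature_cellcount <- function(fixes, temps, grid,
                                       window = time_window("full"),
                                       max_gap = 21600) {
  sum_r <- matrix(0, grid$nx, grid$ny)
  cnt_r <- matrix(0, grid$nx, grid$ny)
  dropped <- 0L
  tl <- .split_animals(temps)
  for (trk in .split_animals(fixes)) {
    te <- tl[[trk$animal_id[1]]]
    if (is.null(te)) next
    te <- te[in_window(window, te$time), , drop = FALSE]
    if (nrow(te) == 0) next
    ft <- as.numeric(trk$time)
    cell <- locate_cell(grid, trk$x, trk$y)
    for (j in seq_len(nrow(te))) {
      d <- abs(ft - as.numeric(te$time[j]))
      i <- which.min(d)
      if (d[i] <= max_gap && !is.na(cell$ix[i])) {
        sum_r[cell$ix[i] + 1L, cell$iy[i] + 1L] <-
          sum_r[cell$ix[i] + 1L, cell$iy[i] + 1L] + te$temp_c[j]
        cnt_r[cell$ix[i] + 1L, cell$iy[i] + 1L] <-
          cnt_r[cell$ix[i] + 1L, cell$iy[i] + 1L] + 1
      } else dropped <- dropped + 1L
    }
  }
  v <- sum_r / cnt_r
  v[cnt_r == 0] <- NA_real_
  list(mean = ud_raster(grid, v, units = "degC"),
       count = ud_raster(grid, cnt_r, units = "samples"),
       dropped = dropped)
}
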