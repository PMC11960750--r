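# Activity-index validation against grazing observations, intensity
# thresholds, bouts, diurnal/fortnight profiles and temperature series.

#' Observed grazing proportion per activity interval
#'
#' Joins per-minute grazing / non-grazing labels to the 30-min activity
#' intervals of the same animal.  An interval qualifies when the fraction
#' of its minutes carrying a label is at least `min_coverage` (default 1:
#' only fully observed periods, partially observed ones are excluded and
#' counted); the grazing proportion is computed over the observed
#' minutes.
#'
#' @param obs Observation minutes (see [read_observation_minutes()]).
#' @param activity Activity samples (`animal_id`, `interval_start`,
#'   `interval_length`, `index`).
#' @param min_coverage Minimum observed fraction of an interval.
#' @return Data frame (`animal_id`, `period_start`, `proportion_grazing`,
#'   `activity_index`, `minutes_observed`) with attribute
#'   `excluded_periods`.
#' @export
grazing_proportions <- function(obs, activity, min_coverage = 1.0) {
  out <- list(); excluded <- 0L
  obs_by <- split(obs, obs$animal_id)
  for (aid in unique(activity$animal_id)) {
    o <- obs_by[[aid]]
    if (is.null(o)) next
    om <- as.numeric(o$minute)
    act <- activity[activity$animal_id == aid, , drop = FALSE]
    for (j in seq_len(nrow(act))) {
      u <- as.numeric(act$interval_start[j])
      len <- act$interval_length[j]
      sel <- om >= u & om < u + len
      n_obs <- sum(sel)
      if (n_obs == 0) next
      if (n_obs < min_coverage * len / 60) { excluded <- excluded + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        animal_id = aid, period_start = act$interval_start[j],
        proportion_grazing = mean(o$label[sel] == "grazing"),
        activity_index = act$index[j], minutes_observed = n_obs,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(animal_id = character(), period_start = as.POSIXct(character()),
               proportion_grazing = numeric(), activity_index = numeric(),
               minutes_observed = integer())
  attr(res, "excluded_periods") <- excluded
  res
}

#' Linear validation fit of activity index on grazing proportion
#'
#' Ordinary least squares of the sensor activity index on the observed
#' proportion of time grazing per 30-min period; the strength of this fit
#' is what licenses reading the index as a grazing-intensity proxy.
#'
#' @param periods Output of [grazing_proportions()].
#' @return List of class `grazing_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided slope t-test, n-2 df), `n`.
#' @export
fit_activity_grazing_line <- function(periods) {
  x <- periods$proportion_grazing
  y <- periods$activity_index
  n <- length(x)
  if (n < 3) stop("need at least 3 periods", call. = FALSE)
  if (var(x) == 0) stop("constant predictor: all proportions equal",
                        call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  se <- sqrt(ss_res / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * pt(-abs(slope / se), n - 2)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, n = n), class = "grazing_fit")
}

#' @export
print.grazing_fit <- function(x, ...) {
  cat(sprintf(
    "activity ~ grazing proportion: slope %.1f, intercept %.1f, R^2 = %.2f, p = %.3g, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Activity-index threshold at a stated grazing proportion
#'
#' Evaluates the validation line at `proportion`: the fitted activity
#' index when that fraction of a 30-min period is spent grazing
#' (`proportion = 0.5` gives the half-time-grazing threshold).
#'
#' @param fit A `grazing_fit`.
#' @param proportion Grazing proportion in `[0, 1]`.
#' @return Fitted activity-index value.
#' @export
threshold_from_fit <- function(fit, proportion) {
  if (fit$slope == 0) stop("zero slope: threshold undefined", call. = FALSE)
  fit$intercept + fit$slope * proportion
}

#' Midpoint threshold between exclusive-behaviour extremes
#'
#' Arithmetic mean of the maximum activity index over exclusively
#' non-grazing periods and the minimum over exclusively grazing periods,
#' rounded half away from zero to an integer count.
#'
#' @param max_nongrazing_index,min_grazing_index Non-negative counts.
#' @return Integer activity-index threshold.
#' @export
midpoint_threshold <- function(max_nongrazing_index, min_grazing_index) {
  stopifnot(max_nongrazing_index >= 0, min_grazing_index >= 0)
  m <- (max_nongrazing_index + min_grazing_index) / 2
  sign(m) * floor(abs(m) + 0.5)
}

#' Classify activity samples as low / high intensity
#'
#' `low` when `index < threshold`, `high` when `index >= threshold`
#' (the boundary goes to `high` so the two classes partition all values).
#' Daily counts use calendar days in UTC plus `tz_offset_hours`.
#'
#' @param activity Activity samples.
#' @param threshold Activity-index threshold (default 2500).
#' @param tz_offset_hours Offset for day boundaries (default 0).
#' @return List with `samples` (input plus `intensity` column) and
#'   `daily` (per animal per day counts of `low` and `high`).
#' @export
classify_intensity <- function(activity, threshold = 2500,
                               tz_offset_hours = 0) {
  stopifnot(threshold > 0)
  s <- activity
  s$intensity <- ifelse(s$index >= threshold, "high", "low")
  day <- as.Date(as.POSIXct(
    as.numeric(s$interval_start) + tz_offset_hours * 3600,
    origin = "1970-01-01", tz = "UTC"))
  agg <- aggregate(list(n = rep(1L, nrow(s))),
                   by = list(animal_id = s$animal_id, day = day,
                             intensity = s$intensity), FUN = sum)
  low <- agg[agg$intensity == "low", c("animal_id", "day", "n")]
  high <- agg[agg$intensity == "high", c("animal_id", "day", "n")]
  names(low)[3] <- "low"; names(high)[3] <- "high"
  daily <- merge(low, high, by = c("animal_id", "day"), all = TRUE)
  daily$low[is.na(daily$low)] <- 0L
  daily$high[is.na(daily$high)] <- 0L
  daily <- daily[order(daily$animal_id, daily$day), , drop = FALSE]
  rownames(daily) <- NULL
  list(samples = s, daily = daily)
}

#' Mean activity index per hour of day
#'
#' Bins samples by the local hour of `interval_start` and averages,
#' optionally per animal and restricted to a window (e.g. one
#' fortnight).
#'
#' @param activity Activity samples.
#' @param group `"combined"` (pool animals) or `"per_animal"`.
#' @param window A [time_window()] restricting which samples enter.
#' @param tz_offset_hours Offset for the hour-of-day clock.
#' @return Data frame with `hour` (0-23), `mean_index`, `n` (and
#'   `animal_id` when per-animal); hours with no samples have `n = 0`
#'   and `NA` mean.
#' @export
hourly_profile <- function(activity, group = c("combined", "per_animal"),
                           window = time_window("full"),
                           tz_offset_hours = 0) {
  group <- match.arg(group)
  s <- activity[in_window(window, activity$interval_start), , drop = FALSE]
  hr <- floor((as.numeric(s$interval_start) / 3600 + tz_offset_hours)) %% 24
  one <- function(d, h) {
    out <- data.frame(hour = 0:23, mean_index = NA_real_, n = 0L)
    if (nrow(d) > 0) {
      m <- tapply(d$index, factor(h, levels = 0:23), mean)
      n <- tapply(rep(1L, nrow(d)), factor(h, levels = 0:23), sum)
      out$mean_index <- as.numeric(m)
      out$n <- ifelse(is.na(n), 0L, as.integer(n))
    }
    out
  }
  if (group == "combined") return(one(s, hr))
  parts <- lapply(split(seq_len(nrow(s)), s$animal_id), function(i) {
    cbind(animal_id = s$animal_id[i[1]], one(s[i, , drop = FALSE], hr[i]))
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks with average ties, Pearson correlation of the ranks, two-sided
#' p-value from the t distribution with n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero rank variance", call. = FALSE)
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Behavioural bouts from per-minute observation labels
#'
#' Maximal same-label runs of consecutive minutes per animal; a gap
#' between observation sessions (non-consecutive minutes) terminates the
#' current bout.
#'
#' @param obs Observation minutes.
#' @return List with `bouts` (data frame `animal_id`, `label`, `start`,
#'   `duration_min`) and `mean_duration_s` (named vector, seconds per
#'   label).
#' @export
extract_bouts <- function(obs) {
  rows <- list()
  for (o in split(obs, obs$animal_id)) {
    o <- o[order(o$minute), , drop = FALSE]
    tmin <- as.numeric(o$minute) / 60
    new_run <- c(TRUE, diff(tmin) != 1 | o$label[-1] != o$label[-nrow(o)])
    run_id <- factor(cumsum(new_run), levels = unique(cumsum(new_run)))
    starts <- as.integer(tapply(seq_len(nrow(o)), run_id, min))
    lens <- as.integer(tapply(rep(1L, nrow(o)), run_id, sum))
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = o$animal_id[1], label = o$label[starts],
      start = o$minute[starts], duration_min = as.integer(lens),
      stringsAsFactors = FALSE)
  }
  bouts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  means <- tapply(bouts$duration_min * 60, bouts$label, mean)
  list(bouts = bouts, mean_duration_s = means)
}

#' Compare collar temperatures to a weather-station hourly series
#'
#' Collar samples are averaged per clock hour, joined to station hours,
#' and compared by Spearman correlation; the mean collar-minus-station
#' offset quantifies the warm bias of an animal-mounted sensor.
#'
#' @param sensor Temperature samples (`time`, `temp_c`; any animals
#'   pooled).
#' @param station Data frame with `time` (hourly POSIXct) and `temp_c`.
#' @return List: `rho`, `p_value`, `offset_c` (mean sensor - station),
#'   `hourly` (joined per-hour data frame).
#' @export
series_compare_temperature <- function(sensor, station) {
  hour_of <- function(t) floor(as.numeric(t) / 3600)
  sh <- hour_of(sensor$time)
  sens <- tapply(sensor$temp_c, sh, mean)
  st <- setNames(station$temp_c, hour_of(station$time))
  common <- intersect(names(sens), names(st))
  if (length(common) == 0)
    stop("no overlapping hours between sensor and station series",
         call. = FALSE)
  hourly <- data.frame(
    hour = as.numeric(common),
    time = as.POSIXct(as.numeric(common) * 3600, origin = "1970-01-01",
                      tz = "UTC"),
    sensor_c = as.numeric(sens[common]),
    station_c = as.numeric(st[common]))
  sp <- spearman_rho(hourly$sensor_c, hourly$station_c)
  list(rho = sp$rho, p_value = sp$p_value,
       offset_c = mean(hourly$sensor_c - hourly$station_c),
       hourly = hourly)
}
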