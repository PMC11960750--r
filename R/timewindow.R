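#' Temporal analysis windows
#'
#' Windows select records by timestamp.  Supported kinds:
#' \describe{
#'   \item{`full`}{everything.}
#'   \item{`hour_of_day`}{`hours`: integer vector of local hours 0-23.}
#'   \item{`time_of_day`}{`name`: one of `night` (00:00:00-05:59:59),
#'     `morning` (06:00:00-11:59:59), `afternoon` (12:00:00-17:59:59),
#'     `evening` (18:00:00-23:59:59).}
#'   \item{`fortnight`}{`k`: 1-based index of a consecutive 14-day block
#'     counted from `origin` (the first record's time when omitted);
#'     `last` marks the final block, which absorbs any partial days
#'     beyond the last full fortnight (days 57-58 of a 58-day study fall
#'     in F4).}
#'   \item{`custom`}{half-open interval `[start, end)`.}
#' }
#' Hour-of-day logic uses UTC plus `tz_offset_hours`.
#'
#' @param kind Window kind, see above.
#' @param name Time-of-day name for `kind = "time_of_day"`.
#' @param hours Hours for `kind = "hour_of_day"`.
#' @param k Fortnight index for `kind = "fortnight"`.
#' @param origin Fortnight origin time (POSIXct).
#' @param last Logical; is `k` the final fortnight (absorbs overflow)?
#' @param start,end Bounds for `kind = "custom"`.
#' @param tz_offset_hours Offset added to UTC before hour-of-day /
#'   day-boundary logic (default 0).
#' @return An object of class `time_window`.
#' @export
time_window <- function(kind = c("full", "hour_of_day", "time_of_day",
                                 "fortnight", "custom"),
                        name = NULL, hours = NULL, k = NULL, origin = NULL,
                        last = FALSE, start = NULL, end = NULL,
                        tz_offset_hours = 0) {
  kind <- match.arg(kind)
  tod <- list(night = 0:5, morning = 6:11, afternoon = 12:17,
              evening = 18:23)
  if (kind == "time_of_day") {
    if (is.null(name) || !name %in% names(tod))
      stop("time_of_day must be one of: ", paste(names(tod), collapse = ", "),
           call. = FALSE)
    hours <- tod[[name]]
  }
  if (kind == "hour_of_day" && is.null(hours))
    stop("hour_of_day window needs 'hours'", call. = FALSE)
  if (kind == "fortnight" && is.null(k))
    stop("fortnight window needs 'k'", call. = FALSE)
  structure(list(kind = kind, name = name, hours = hours, k = k,
                 origin = origin, last = last, start = start, end = end,
                 tz_offset_hours = tz_offset_hours),
            class = "time_window")
}

#' Test timestamps against a window
#'
#' @param window A [time_window()].
#' @param times POSIXct vector (UTC).
#' @return Logical vector.
#' @export
in_window <- function(window, times) {
  stopifnot(inherits(window, "time_window"))
  local <- as.numeric(times) + window$tz_offset_hours * 3600
  switch(window$kind,
    full = rep(TRUE, length(times)),
    hour_of_day = ,
    time_of_day = (floor(local / 3600) %% 24) %in% window$hours,
    fortnight = {
      origin <- window$origin
      if (is.null(origin)) origin <- min(times)
      d <- as.numeric(times) - as.numeric(origin)
      idx <- floor(d / (14 * 86400)) + 1
      if (isTRUE(window$last)) d >= 0 & idx >= window$k
      else idx == window$k
    },
    custom = times >= window$start & times < window$end)
}
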