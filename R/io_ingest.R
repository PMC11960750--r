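#' @importFrom stats aggregate cor median optimize pnorm pt qnorm
#'   rbinom rgamma rnorm runif sd setNames var rexp
#' @importFrom utils read.csv write.csv head tail
NULL

EARTH_RADIUS_M <- 6371000

.parse_time <- function(x) {
  # ISO-8601, "T" or space separated, optional trailing "Z"
  x <- sub("Z$", "", sub("T", " ", as.character(x)))
  tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                              "%Y-%m-%d")),
    error = function(e) as.POSIXct(rep(NA_real_, length(x)),
                                   origin = "1970-01-01", tz = "UTC"))
}

.format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE,
           check.names = FALSE, fileEncoding = "UTF-8")
}

#' Reference point for the local map projection
#'
#' A reference latitude/longitude (typically the centre of the study field)
#' about which all fixes are projected to local metric coordinates.
#'
#' @param lat0,lon0 Reference latitude and longitude in decimal degrees
#'   (WGS84).
#' @return An object of class `ref_point`.
#' @export
ref_point <- function(lat0, lon0) {
  stopifnot(is.finite(lat0), is.finite(lon0),
            lat0 >= -90, lat0 <= 90, lon0 >= -180, lon0 <= 180)
  structure(list(lat0 = lat0, lon0 = lon0), class = "ref_point")
}

#' Read collar telemetry from a canonical CSV export
#'
#' Parses a delimited text export holding the three collar data streams in
#' long format: GPS position fixes, 30-minute cumulative activity-index
#' counts, and instantaneous collar temperature.  The canonical schema has
#' columns `animal_id`, `time` (ISO-8601, UTC), `record_type` (one of
#' `fix`, `activity`, `temperature`), `lat`, `lon`, `activity_index`,
#' `temp_c`; unused fields are left empty.  A column-name mapping can adapt
#' other exports to this schema.
#'
#' Records are sorted by `(animal_id, time)` within each stream.  Exact
#' duplicate `(animal_id, time)` pairs within a stream are deduplicated
#' keeping the first occurrence; the number dropped is reported via the
#' `dropped` attribute and a warning.
#'
#' @param path Path to a comma- or tab-delimited UTF-8 file.
#' @param schema Named character vector mapping canonical column names to
#'   the file's column names, e.g. `c(animal_id = "serial_no")`.  Unmapped
#'   canonical names are looked up verbatim.
#' @param interval_length Activity accumulation interval in seconds
#'   (default 1800, i.e. 30 min).
#' @return A list with data frames `fixes` (`animal_id`, `time`, `lat`,
#'   `lon`), `activity` (`animal_id`, `interval_start`, `interval_length`,
#'   `index`) and `temperature` (`animal_id`, `time`, `temp_c`), plus a
#'   `counts` list of rows read and dropped per stream.
#' @export
read_collar_records <- function(path, schema = NULL, interval_length = 1800) {
  df <- .read_delim_auto(path)
  canonical <- c("animal_id", "time", "record_type", "lat", "lon",
                 "activity_index", "temp_c")
  colmap <- setNames(canonical, canonical)
  if (!is.null(schema)) colmap[names(schema)] <- schema
  need <- c("animal_id", "time", "record_type")
  for (nm in need) {
    if (!colmap[[nm]] %in% names(df))
      stop("schema error: required column '", colmap[[nm]],
           "' (", nm, ") not found", call. = FALSE)
  }
  get_col <- function(nm) {
    if (colmap[[nm]] %in% names(df)) df[[colmap[[nm]]]] else
      rep(NA, nrow(df))
  }
  tm <- .parse_time(get_col("time"))
  bad <- which(is.na(tm))
  if (length(bad) > 0)
    stop("unparseable timestamp at data row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  rec <- tolower(trimws(as.character(get_col("record_type"))))
  unknown <- setdiff(unique(rec), c("fix", "activity", "temperature"))
  if (length(unknown) > 0)
    stop("unknown record_type value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  aid <- as.character(get_col("animal_id"))

  take <- function(kind) which(rec == kind)
  dedupe <- function(d) {
    o <- order(d$animal_id, d$time)
    d <- d[o, , drop = FALSE]
    dup <- duplicated(paste(d$animal_id, as.numeric(d$time)))
    n_drop <- sum(dup)
    if (n_drop > 0)
      warning(sprintf("dropped %d duplicate (animal, time) record(s), kept first",
                      n_drop), call. = FALSE)
    d <- d[!dup, , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "dropped") <- n_drop
    d
  }

  i <- take("fix")
  fixes <- data.frame(animal_id = aid[i], time = tm[i],
                      lat = as.numeric(get_col("lat")[i]),
                      lon = as.numeric(get_col("lon")[i]),
                      stringsAsFactors = FALSE)
  if (nrow(fixes) > 0) {
    if (any(!is.finite(fixes$lat) | !is.finite(fixes$lon)))
      stop("fix row with missing lat/lon", call. = FALSE)
    if (any(abs(fixes$lat) > 90 | abs(fixes$lon) > 180))
      stop("lat/lon outside valid range", call. = FALSE)
  }
  fixes <- dedupe(fixes)

  i <- take("activity")
  act_idx <- as.numeric(get_col("activity_index")[i])
  if (any(!is.finite(act_idx)))
    stop("activity row with missing activity_index", call. = FALSE)
  if (any(act_idx < 0))
    stop("validation error: negative activity index", call. = FALSE)
  activity <- data.frame(animal_id = aid[i], interval_start = tm[i],
                         interval_length = rep(interval_length, length(i)),
                         index = act_idx, stringsAsFactors = FALSE)
  names(activity)[2] <- "interval_start"
  colnames(activity) <- c("animal_id", "interval_start", "interval_length",
                          "index")
  activity$time <- activity$interval_start  # sort key alias for dedupe
  activity <- dedupe(activity)
  nd <- attr(activity, "dropped")
  activity$time <- NULL
  attr(activity, "dropped") <- nd

  i <- take("temperature")
  tc <- as.numeric(get_col("temp_c")[i])
  if (any(!is.finite(tc)))
    stop("temperature row with missing temp_c", call. = FALSE)
  temperature <- data.frame(animal_id = aid[i], time = tm[i], temp_c = tc,
                            stringsAsFactors = FALSE)
  temperature <- dedupe(temperature)

  list(fixes = fixes, activity = activity, temperature = temperature,
       counts = list(
         fixes = nrow(fixes), activity = nrow(activity),
         temperature = nrow(temperature),
         dropped = attr(fixes, "dropped") + attr(activity, "dropped") +
           attr(temperature, "dropped")))
}

#' Write collar streams back to the canonical CSV format
#'
#' Inverse of [read_collar_records()]: the written file re-reads to
#' field-for-field identical records.
#'
#' @param streams List with `fixes`, `activity`, `temperature` data frames
#'   as returned by [read_collar_records()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_collar_records <- function(streams, path) {
  blank <- function(n) rep("", n)
  f <- streams$fixes; a <- streams$activity; te <- streams$temperature
  rows <- rbind(
    data.frame(animal_id = f$animal_id, time = .format_time(f$time),
               record_type = "fix", lat = f$lat, lon = f$lon,
               activity_index = blank(nrow(f)), temp_c = blank(nrow(f)),
               stringsAsFactors = FALSE),
    data.frame(animal_id = a$animal_id, time = .format_time(a$interval_start),
               record_type = "activity", lat = blank(nrow(a)),
               lon = blank(nrow(a)), activity_index = a$index,
               temp_c = blank(nrow(a)), stringsAsFactors = FALSE),
    data.frame(animal_id = te$animal_id, time = .format_time(te$time),
               record_type = "temperature", lat = blank(nrow(te)),
               lon = blank(nrow(te)), activity_index = blank(nrow(te)),
               temp_c = te$temp_c, stringsAsFactors = FALSE))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project fixes to local metric coordinates
#'
#' Applies a local equirectangular projection about a reference point:
#' `x = R cos(lat0) (lon - lon0)` and `y = R (lat - lat0)` with angles in
#' radians and `R = 6,371,000` m.  For a field a few hundred metres across
#' the planar distance error versus the great-circle distance is far below
#' the 15 m grid-cell size.
#'
#' @param fixes Data frame with `lat`, `lon` columns.
#' @param ref A [ref_point()].
#' @return `fixes` with `x`, `y` columns (metres east/north of `ref`) added.
#' @export
project_coordinates <- function(fixes, ref) {
  if (missing(ref) || !inherits(ref, "ref_point"))
    stop("a ref_point is required", call. = FALSE)
  d2r <- pi / 180
  if (nrow(fixes) > 0 && any(abs(fixes$lat - ref$lat0) > 1))
    warning("fix more than 1 degree latitude from the reference point; ",
            "projection distortion outside design envelope", call. = FALSE)
  fixes$x <- EARTH_RADIUS_M * cos(ref$lat0 * d2r) *
    (fixes$lon - ref$lon0) * d2r
  fixes$y <- EARTH_RADIUS_M * (fixes$lat - ref$lat0) * d2r
  fixes
}

#' Inverse of [project_coordinates()]
#'
#' @param xy Data frame with `x`, `y` columns in metres.
#' @param ref A [ref_point()].
#' @return `xy` with `lat`, `lon` columns recovered.
#' @export
unproject_coordinates <- function(xy, ref) {
  d2r <- pi / 180
  xy$lon <- ref$lon0 + xy$x / (EARTH_RADIUS_M * cos(ref$lat0 * d2r)) / d2r
  xy$lat <- ref$lat0 + xy$y / EARTH_RADIUS_M / d2r
  xy
}

#' Great-circle (haversine) distance in metres
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in metres.
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  d2r <- pi / 180
  dlat <- (lat2 - lat1) * d2r
  dlon <- (lon2 - lon1) * d2r
  a <- sin(dlat / 2)^2 + cos(lat1 * d2r) * cos(lat2 * d2r) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Read per-minute behavioural observation labels
#'
#' Reads an observation CSV with columns `animal_id`, `minute` (ISO-8601,
#' truncated to the minute), `label` (`grazing` / `non_grazing`,
#' case-insensitive; `non-grazing` and `nongrazing` are accepted spellings)
#' and `observer_id`.  Gaps between observation sessions are preserved.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return Data frame of class `obs_minutes` with normalized labels, sorted
#'   by `(animal_id, minute)`.
#' @export
read_observation_minutes <- function(path) {
  df <- .read_delim_auto(path)
  need <- c("animal_id", "minute", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lab <- tolower(trimws(as.character(df$label)))
  lab[lab %in% c("non-grazing", "nongrazing", "non grazing")] <- "non_grazing"
  bad <- setdiff(unique(lab), c("grazing", "non_grazing"))
  if (length(bad) > 0)
    stop("unknown observation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  minute <- .parse_time(df$minute)
  if (any(is.na(minute)))
    stop("unparseable minute timestamp", call. = FALSE)
  minute <- as.POSIXct(floor(as.numeric(minute) / 60) * 60,
                       origin = "1970-01-01", tz = "UTC")
  out <- data.frame(animal_id = as.character(df$animal_id), minute = minute,
                    label = lab,
                    observer_id = if ("observer_id" %in% names(df))
                      as.character(df$observer_id) else NA_character_,
                    stringsAsFactors = FALSE)
  key <- paste(out$animal_id, as.numeric(out$minute))
  if (anyDuplicated(key)) {
    split_lab <- tapply(out$label, key, function(l) length(unique(l)))
    if (any(split_lab > 1))
      stop("conflicting labels for the same animal-minute", call. = FALSE)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out <- out[order(out$animal_id, out$minute), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("obs_minutes", class(out))
  out
}
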