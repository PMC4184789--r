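#' Convert tag pressure readings to depth
#'
#' Archival tags log pressure in psi; depth is recovered with the seawater
#' conversion 1 m = 1.46 psi (seawater density 1.025e3 kg m-3).
#'
#' @param p_psi pressure(s), psi, >= 0.
#' @return depth in metres.
#' @examples
#' pressure_to_depth(14.6) # 10 m
#' @export
pressure_to_depth <- function(p_psi) {
  if (any(!is.finite(p_psi)) || any(p_psi < 0)) {
    stop_input("pressure must be non-negative")
  }
  p_psi / 1.46
}

#' Interpolate daily positions along a geolocation track
#'
#' Fits a piece-wise linear curve in latitude/longitude through the ordered
#' anchor points of a track (release position, sequential geolocations and,
#' where available, the recapture position) and returns one position per
#' calendar day spanned. A single anchor yields a constant daily position.
#' Planar interpolation is used: at North Sea scales the great-circle
#' correction is far below the half-degree grid resolution.
#'
#' @param track data.frame with columns `date` (Date or ISO-8601 character),
#'   `lat`, `lon`, ordered or orderable by date; an optional `anchor_type`
#'   column (`release`/`geolocation`/`recapture`) is carried through.
#' @return data.frame with one row per day: `date`, `lat`, `lon`.
#' @export
daily_positions <- function(track) {
  if (!nrow(track)) stop_input("track has no anchor points")
  track$date <- as.Date(track$date)
  track <- track[order(track$date), ]
  if (anyDuplicated(track$date)) {
    stop_input("duplicated anchor dates: %s",
               paste(track$date[duplicated(track$date)], collapse = ", "))
  }
  days <- seq(min(track$date), max(track$date), by = "day")
  if (nrow(track) == 1L) {
    return(data.frame(date = days, lat = track$lat, lon = track$lon))
  }
  t0 <- as.numeric(track$date)
  td <- as.numeric(days)
  data.frame(
    date = days,
    lat = stats::approx(t0, track$lat, xout = td)$y,
    lon = stats::approx(t0, track$lon, xout = td)$y)
}

#' Estimate fish age from annual band count and capture date
#'
#' Ages are referred to a common notional birth date (default 1 February,
#' the peak spawning period): age = number of complete annual growth bands
#' plus the fraction of a year (days / 365) elapsed since the most recent
#' notional birthday before capture, reported to 0.1 year.
#'
#' @param band_count integer >= 0, complete annual bands counted.
#' @param capture_date capture date (Date or ISO-8601 character).
#' @param birth_month,birth_day notional birth date parts (defaults Feb 1).
#' @return age in years, rounded to one decimal.
#' @examples
#' estimate_age(14, "1999-05-15") # 14.3
#' @export
estimate_age <- function(band_count, capture_date,
                         birth_month = 2, birth_day = 1) {
  if (any(band_count < 0) || any(band_count != round(band_count))) {
    stop_input("band_count must be a non-negative integer")
  }
  capture_date <- as.Date(capture_date)
  yr <- as.integer(format(capture_date, "%Y"))
  bday <- as.Date(sprintf("%d-%02d-%02d", yr, birth_month, birth_day))
  bday[capture_date < bday] <-
    as.Date(sprintf("%d-%02d-%02d", yr - 1, birth_month, birth_day))[capture_date < bday]
  frac <- as.numeric(capture_date - bday) / 365
  round(band_count + frac, 1)
}

#' Read archival-tag time series and geolocation tracks
#'
#' `read_tag_records()` expects `fish_id, timestamp, temperature_c,
#' pressure_psi` (ISO-8601 timestamps); `read_tracks()` expects `fish_id,
#' anchor_type, date, lat, lon`. Both validate schema and report row counts.
#'
#' @param path delimited text file (comma-separated, header row).
#' @return data.frame; tag records gain a `POSIXct` `timestamp` (UTC) and a
#'   `depth_m` column derived from pressure.
#' @export
read_tag_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "timestamp", "temperature_c", "pressure_psi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("%s: missing columns %s", path,
                               paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  if (any(is.na(df$timestamp))) stop_input("%s: unparseable timestamps", path)
  df$depth_m <- pressure_to_depth(df$pressure_psi)
  message(sprintf("read_tag_records: %d rows from %s", nrow(df), path))
  df
}

#' @rdname read_tag_records
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "anchor_type", "date", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("%s: missing columns %s", path,
                               paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  message(sprintf("read_tracks: %d rows from %s", nrow(df), path))
  df
}

#' Daily mean temperatures from a high-frequency tag record
#'
#' Collapses a (typically 10-minute cadence) temperature series to daily
#' means, the resolution at which otolith d18O predictions are made.
#'
#' @param tag data.frame with `timestamp` (POSIXct) and `temperature_c`.
#' @return data.frame with `date` and `temperature_c` (daily mean).
#' @export
daily_mean_temperature <- function(tag) {
  stopifnot(all(c("timestamp", "temperature_c") %in% names(tag)))
  d <- as.Date(tag$timestamp, tz = "UTC")
  agg <- tapply(tag$temperature_c, d, mean)
  data.frame(date = as.Date(names(agg)), temperature_c = as.numeric(agg),
             row.names = NULL)
}
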