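# NOAA general solar position calculations (fractional-year expansion of
# the equation of time and solar declination, zenith 90.833 deg for the
# official sunrise/sunset including refraction and solar radius).

#' Sunrise and sunset times (NOAA algorithm)
#'
#' Computes official sunrise and sunset (solar zenith 90.833 degrees,
#' i.e. refraction-corrected) for a calendar date at a geographic
#' position, using the NOAA low-precision solar equations. Accuracy is
#' on the order of a minute at mid latitudes, ample for labelling
#' half-hourly telemetry as day or night.
#'
#' @param date a `Date` vector (the civil date at the location).
#' @param lat,lon latitude and longitude in decimal degrees
#'   (longitude positive east). Latitudes poleward of 66.5 degrees are
#'   rejected: the study band has no polar day or night.
#' @param tz_offset_hours fixed UTC offset of local clock time, hours
#'   (default -7, Mountain Standard Time).
#' @return A tibble with columns `date`, `sunrise`, `sunset` (POSIXct, UTC).
#' @export
sun_times <- function(date, lat, lon, tz_offset_hours = -7) {
  stopifnot(inherits(date, "Date"))
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(date, n)
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)
  if (any(!is.finite(lat)) || any(abs(lat) >= 66.5)) {
    abort("sun_times() supports latitudes strictly within +/-66.5 degrees (no polar day/night).")
  }
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  yr <- as.integer(strftime(date, "%Y", tz = "UTC"))
  ndays <- ifelse(yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0), 366, 365)
  # fractional year, radians, evaluated at local solar noon-ish (hour 12)
  g <- 2 * pi / ndays * (doy - 1 + (12 - 0) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) - tan(latr) * tan(decl)
  if (any(abs(cos_ha) > 1)) {
    abort("No sunrise/sunset on this date at this latitude; latitude unsupported.")
  }
  ha <- acos(cos_ha) * 180 / pi # degrees
  sunrise_min <- 720 - 4 * (lon + ha) - eqtime # minutes after 00:00 UTC
  sunset_min <- 720 - 4 * (lon - ha) - eqtime
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  tibble::tibble(
    date = date,
    sunrise = day0 + sunrise_min * 60,
    sunset = day0 + sunset_min * 60
  )
}

#' Classify timestamps as day or night
#'
#' A timestamp is "day" iff sunrise <= t < sunset for the local civil date
#' at the given coordinates; otherwise "night". For telemetry, coordinates
#' should be the wolf's daily centroid so one sunrise/sunset pair applies
#' to the whole wolf-day.
#'
#' @param timestamp POSIXct vector (UTC).
#' @param lat,lon decimal degrees (recycled against `timestamp`).
#' @param tz_offset_hours fixed UTC offset used to pick the civil date.
#' @return Character vector of `"day"` / `"night"`.
#' @export
classify_time_of_day <- function(timestamp, lat, lon, tz_offset_hours = -7) {
  stopifnot(inherits(timestamp, "POSIXct"))
  n <- length(timestamp)
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)
  local_date <- as.Date(timestamp + tz_offset_hours * 3600, tz = "UTC")
  st <- sun_times(local_date, lat, lon, tz_offset_hours)
  ifelse(timestamp >= st$sunrise & timestamp < st$sunset, "day", "night")
}
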