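# Telemetry ingestion and regularization: cleaning, thinning to a common
# 30-min grid, step speeds, camera-day labelling and daily centroids.

.FIX_COLUMNS <- c("wolf_id", "timestamp", "easting", "northing", "lat", "lon")

#' Read a telemetry CSV of GPS fixes
#'
#' Expects the header `wolf_id,timestamp,easting,northing,lat,lon` with
#' ISO-8601 UTC timestamps, projected coordinates in meters and geographic
#' coordinates in decimal degrees. Rows are sorted by wolf and time and
#' exact duplicate rows are dropped with a warning.
#'
#' @param path path to the CSV file.
#' @return A tibble of fixes.
#' @export
read_fixes <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.FIX_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Telemetry file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  formats <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
               "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")
  parsed <- lapply(formats, function(f) {
    as.POSIXct(strptime(raw$timestamp, f, tz = "UTC"))
  })
  ts <- parsed[[which.max(vapply(parsed, function(p) sum(!is.na(p)), numeric(1)))]]
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    abort(sprintf("Unparseable timestamp '%s' at row %d of %s",
                  raw$timestamp[bad], bad, path))
  }
  for (col in c("easting", "northing", "lat", "lon")) {
    if (!is.numeric(raw[[col]]) || any(!is.finite(raw[[col]]))) {
      abort(sprintf("Column '%s' must be finite numeric", col))
    }
  }
  if (any(abs(raw$lat) > 90) || any(abs(raw$lon) > 180)) {
    abort("Geographic coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  }
  fixes <- tibble::tibble(
    wolf_id = as.character(raw$wolf_id),
    timestamp = ts,
    easting = raw$easting, northing = raw$northing,
    lat = raw$lat, lon = raw$lon
  )
  n0 <- nrow(fixes)
  fixes <- distinct(fixes)
  if (nrow(fixes) < n0) {
    warn(sprintf("Dropped %d exact duplicate fix row(s)", n0 - nrow(fixes)))
  }
  # duplicate timestamps within a wolf (distinct positions): keep first
  fixes <- fixes %>%
    arrange(.data$wolf_id, .data$timestamp) %>%
    group_by(.data$wolf_id) %>%
    filter(!duplicated(.data$timestamp)) %>%
    ungroup()
  inform(sprintf("Read %d fixes for %d wolves from %s",
                 nrow(fixes), length(unique(fixes$wolf_id)), path))
  fixes
}

#' Write fixes in the telemetry CSV dialect
#' @param fixes a fix tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes[, .FIX_COLUMNS]
  out$timestamp <- strftime(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Thin fixes to a regular interval
#'
#' Retains, per wolf, the fix nearest each grid time (grid anchored at the
#' top of the hour: :00 and :30 for the 30-min default), at most one fix
#' per grid slot. Data already on the target grid pass through unchanged;
#' ties (two fixes equidistant from a slot time) keep the earlier fix.
#'
#' @param fixes fix tibble sorted by wolf and time.
#' @param target_min grid spacing in minutes (default 30).
#' @return The thinned fix tibble.
#' @export
thin_to_interval <- function(fixes, target_min = 30) {
  stopifnot(target_min > 0)
  step_s <- target_min * 60
  secs <- as.numeric(fixes$timestamp)
  # nearest grid time; a fix exactly midway is assigned to the later slot
  slot <- floor(secs / step_s + 0.5) * step_s
  off <- abs(secs - slot)
  fixes %>%
    mutate(.slot = slot, .off = off) %>%
    arrange(.data$wolf_id, .data$.slot, .data$.off, .data$timestamp) %>%
    group_by(.data$wolf_id, .data$.slot) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$wolf_id, .data$timestamp) %>%
    select(-".slot", -".off")
}

#' Camera-day date of a timestamp
#'
#' The snow cameras photograph once daily at noon, so a photo summarizes
#' snowfall over the preceding 24 h. Telemetry after local noon can only
#' be matched to the next day's photo: fixes strictly after 12:00:00 local
#' are assigned to the following calendar date; a fix at exactly noon
#' keeps its date (the noon photo is contemporaneous).
#'
#' @param timestamp POSIXct (UTC).
#' @param tz_offset_hours fixed UTC offset of local clock time (default -7).
#' @return A `Date` vector.
#' @export
assign_camera_day <- function(timestamp, tz_offset_hours = -7) {
  stopifnot(inherits(timestamp, "POSIXct"))
  secs <- as.numeric(timestamp) + tz_offset_hours * 3600
  day <- floor(secs / 86400)
  secs_into_day <- secs - day * 86400
  as.Date(day, origin = "1970-01-01") + ifelse(secs_into_day > 12 * 3600, 1L, 0L)
}

#' Compute steps (speeds between consecutive fixes)
#'
#' One step per consecutive fix pair within a wolf: Euclidean distance on
#' the projected coordinates divided by the elapsed minutes. Steps whose
#' interval falls outside `interval_band` (gaps, missed fixes) are dropped
#' and counted in a message. Each step carries the camera-day of its end
#' fix.
#'
#' @param fixes thinned fix tibble.
#' @param interval_band numeric length-2, acceptable interval in minutes
#'   (default `c(19.75, 40.92)`, the observed range after 30-min thinning).
#' @param tz_offset_hours fixed UTC offset for camera-day assignment.
#' @return A step tibble with columns `wolf_id`, `t_start`, `t_end`,
#'   `interval_min`, `distance_m`, `speed_mpm`, `camera_day`.
#' @export
compute_steps <- function(fixes, interval_band = c(19.75, 40.92),
                          tz_offset_hours = -7) {
  stopifnot(length(interval_band) == 2, interval_band[1] > 0,
            interval_band[1] <= interval_band[2])
  singletons <- fixes %>% group_by(.data$wolf_id) %>%
    summarise(n = dplyr::n()) %>% filter(n < 2)
  if (nrow(singletons) > 0) {
    warn(sprintf("%d wolf/wolves with a single fix yield no steps", nrow(singletons)))
  }
  steps <- fixes %>%
    arrange(.data$wolf_id, .data$timestamp) %>%
    group_by(.data$wolf_id) %>%
    mutate(
      t_start = dplyr::lag(.data$timestamp),
      interval_min = as.numeric(difftime(.data$timestamp, .data$t_start, units = "mins")),
      distance_m = sqrt((.data$easting - dplyr::lag(.data$easting))^2 +
                          (.data$northing - dplyr::lag(.data$northing))^2)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$t_start))
  n_all <- nrow(steps)
  steps <- filter(steps, .data$interval_min >= interval_band[1],
                  .data$interval_min <= interval_band[2])
  if (n_all > nrow(steps)) {
    inform(sprintf("Excluded %d step(s) with intervals outside [%.2f, %.2f] min",
                   n_all - nrow(steps), interval_band[1], interval_band[2]))
  }
  steps %>%
    mutate(
      speed_mpm = .data$distance_m / .data$interval_min,
      camera_day = assign_camera_day(.data$timestamp, tz_offset_hours)
    ) %>%
    select("wolf_id", t_start = "t_start", t_end = "timestamp",
           "interval_min", "distance_m", "speed_mpm", "camera_day")
}

#' Daily centroid locations
#'
#' Arithmetic mean of the projected coordinates per wolf and camera-day;
#' geographic coordinates are averaged likewise (equivalent under the
#' locally linear projection the pipeline assumes).
#'
#' @param fixes fix tibble (camera-day computed internally if absent).
#' @param tz_offset_hours fixed UTC offset for camera-day assignment.
#' @return tibble with `wolf_id`, `camera_day`, `easting`, `northing`,
#'   `lat`, `lon`, `n_fixes`.
#' @export
daily_centroids <- function(fixes, tz_offset_hours = -7) {
  if (!"camera_day" %in% names(fixes)) {
    fixes <- mutate(fixes, camera_day = assign_camera_day(.data$timestamp, tz_offset_hours))
  }
  fixes %>%
    group_by(.data$wolf_id, .data$camera_day) %>%
    summarise(
      easting = mean(.data$easting), northing = mean(.data$northing),
      lat = mean(.data$lat), lon = mean(.data$lon),
      n_fixes = dplyr::n(), .groups = "drop"
    )
}

#' Label steps day/night at the daily centroid
#'
#' Joins steps to their wolf-day centroid and classifies the step's end
#' time against sunrise/sunset evaluated at the centroid coordinates.
#'
#' @param steps step tibble with `camera_day`.
#' @param centroids output of [daily_centroids()].
#' @param tz_offset_hours fixed UTC offset.
#' @return `steps` with a `time_of_day` column (`"day"`/`"night"`).
#' @export
label_time_of_day <- function(steps, centroids, tz_offset_hours = -7) {
  ctr <- select(centroids, "wolf_id", "camera_day", ctr_lat = "lat", ctr_lon = "lon")
  steps %>%
    left_join(ctr, by = c("wolf_id", "camera_day")) %>%
    mutate(time_of_day = classify_time_of_day(.data$t_end, .data$ctr_lat,
                                              .data$ctr_lon, tz_offset_hours)) %>%
    select(-"ctr_lat", -"ctr_lon")
}
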