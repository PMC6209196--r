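# Camera snow series: daily depth -> 24-h accumulation -> snowfall events
# (>= 5 cm / 24 h), and the nearest-camera join that gives each wolf-day
# exactly one snow depth and one accumulation value.

.DEPLOY_COLUMNS <- c("camera_id", "easting", "northing", "lat", "lon",
                     "deploy_date", "initial_depth_cm")

#' Read camera deployment metadata
#' @param path CSV with header
#'   `camera_id,easting,northing,lat,lon,deploy_date,initial_depth_cm`.
#' @return A tibble of deployments.
#' @export
read_deployments <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.DEPLOY_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Deployment file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw)
  out$camera_id <- as.character(out$camera_id)
  out$deploy_date <- as.Date(out$deploy_date)
  if (anyNA(out$deploy_date)) abort("Unparseable deploy_date in deployment file")
  if (any(out$initial_depth_cm < 0)) abort("initial_depth_cm must be >= 0")
  out
}

#' Read daily snow-depth readings
#' @param path CSV with header `camera_id,date,depth_cm`.
#' @return A tibble of readings.
#' @export
read_depths <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("camera_id", "date", "depth_cm"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("Depth file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw)
  out$camera_id <- as.character(out$camera_id)
  out$date <- as.Date(out$date)
  if (anyNA(out$date)) abort("Unparseable date in depth file")
  out
}

#' Daily accumulation and snowfall-event flags per camera
#'
#' Accumulation is the first difference of depth over exactly 24 h; the
#' first day of a series, and any day following a gap of more than one
#' day, has missing accumulation. A day is a snowfall event iff its
#' accumulation is at or above the threshold. Negative accumulation
#' (settling, melt) is kept and can never trigger an event.
#'
#' @param readings tibble `camera_id,date,depth_cm`.
#' @param deployments optional deployment tibble for validation
#'   (readings before a camera's deploy date are an error).
#' @param event_threshold_cm event threshold, cm per 24 h (default 5).
#' @return tibble `camera_id,date,depth_cm,accumulation_cm,is_event`.
#' @export
build_snow_daily <- function(readings, deployments = NULL, event_threshold_cm = 5) {
  stopifnot(event_threshold_cm > 0)
  if (any(readings$depth_cm < 0, na.rm = TRUE)) abort("depth_cm must be >= 0")
  dup <- readings %>% group_by(.data$camera_id, .data$date) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate (camera_id, date) reading: %s %s",
                  dup$camera_id[1], format(dup$date[1])))
  }
  if (!is.null(deployments)) {
    chk <- left_join(readings, select(deployments, "camera_id", "deploy_date"),
                     by = "camera_id")
    early <- filter(chk, !is.na(.data$deploy_date), .data$date < .data$deploy_date)
    if (nrow(early) > 0) {
      abort(sprintf("Reading before deployment: camera %s on %s",
                    early$camera_id[1], format(early$date[1])))
    }
  }
  readings %>%
    arrange(.data$camera_id, .data$date) %>%
    group_by(.data$camera_id) %>%
    mutate(
      .gap = as.integer(.data$date - dplyr::lag(.data$date)),
      accumulation_cm = ifelse(!is.na(.data$.gap) & .data$.gap == 1L,
                               .data$depth_cm - dplyr::lag(.data$depth_cm), NA_real_),
      is_event = .data$accumulation_cm >= event_threshold_cm
    ) %>%
    ungroup() %>%
    select("camera_id", "date", "depth_cm", "accumulation_cm", "is_event")
}

#' Nearest active camera for each daily centroid
#'
#' Euclidean distance on projected coordinates; only cameras deployed on
#' or before the centroid's camera-day are candidates; ties go to the
#' lexicographically smallest camera id.
#'
#' @param centroids output of [daily_centroids()].
#' @param deployments deployment tibble.
#' @return `centroids` with `camera_id` and `distance_km` columns.
#' @export
nearest_camera <- function(centroids, deployments) {
  stopifnot(nrow(deployments) >= 1)
  deployments <- arrange(deployments, .data$camera_id)
  res <- lapply(seq_len(nrow(centroids)), function(i) {
    active <- filter(deployments, .data$deploy_date <= centroids$camera_day[i])
    if (nrow(active) == 0) {
      abort(sprintf("No camera active on %s", format(centroids$camera_day[i])))
    }
    d <- sqrt((active$easting - centroids$easting[i])^2 +
                (active$northing - centroids$northing[i])^2)
    j <- which.min(d) # first minimum = smallest camera_id after sort
    list(camera_id = active$camera_id[j], distance_km = d[j] / 1000)
  })
  centroids$camera_id <- vapply(res, `[[`, character(1), "camera_id")
  centroids$distance_km <- vapply(res, `[[`, numeric(1), "distance_km")
  centroids
}

#' Join snow values to wolf-days via the nearest camera
#'
#' One row per (wolf, camera-day). Days whose nearest camera lacks a
#' reading on that date keep missing depth/accumulation; camera-to-wolf
#' distances are reported as a data-quality summary.
#'
#' @param centroids output of [daily_centroids()].
#' @param snow_daily output of [build_snow_daily()].
#' @param deployments deployment tibble.
#' @return tibble `wolf_id,camera_day,camera_id,distance_km,depth_cm,
#'   accumulation_cm,is_event`.
#' @export
join_wolf_day <- function(centroids, snow_daily, deployments) {
  with_cam <- nearest_camera(centroids, deployments)
  out <- with_cam %>%
    left_join(snow_daily, by = c("camera_id" = "camera_id", "camera_day" = "date")) %>%
    select("wolf_id", "camera_day", "camera_id", "distance_km",
           "depth_cm", "accumulation_cm", "is_event")
  inform(sprintf("Nearest-camera distances: mean %.1f km, sd %.1f km (n = %d wolf-days)",
                 mean(out$distance_km), sd(out$distance_km), nrow(out)))
  out
}
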