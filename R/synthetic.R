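# Synthetic collar and camera data with the statistical structure the
# pipeline assumes: 17 wolves over a ~60-day winter at 10- or 30-min fix
# rates, two-state (rest/travel) movement with log10-normal speeds and
# per-wolf random effects, and 13-14 cameras whose daily depth series
# contain localized >= 5 cm / 24 h snowfall events.

.default_behavior_model <- function() {
  list(
    intercept = -0.467, # logit P(travel), daytime on the event day
    night = -0.542,
    category = c(control = -0.243, two_before = -0.201, one_before = -0.026,
                 one_after = -0.025, two_after = -0.169, three_after = -0.095),
    night_by_category = c(control = 0.563, two_before = 0.456, one_before = 0.365,
                          one_after = 0.268, two_after = 0.621, three_after = 0.546),
    ranef_intercept_sd = 0.3
  )
}

.default_speed_model <- function() {
  list(
    intercept = 1.081, # log10 m/min, daytime travel on the event day
    night = 0.107,
    category = c(control = 0.061, two_before = 0.037, one_before = 0.045,
                 one_after = 0.005, two_after = 0.041, three_after = -0.016),
    ranef_intercept_sd = 0.10,
    ranef_night_sd = 0.05
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 17 wolves over 60 winter days at
#' 30-min fixes, 14 snow cameras, localized snowfall events of 5-16 cm
#' with about half shared across cameras, rest/travel speed modes at
#' 10^-0.3 and 10^1.3 m/min bracketing the 1.65 m/min cutoff, and
#' behaviour/speed covariate effects (night, snowfall category, per-wolf
#' random effects) on the published coefficient scale.
#'
#' `behavior_model = NULL` draws states i.i.d. from the mixture weights;
#' `speed_model = NULL` draws travel speeds from the plain travel
#' component. Both are useful for parameter-recovery checks.
#'
#' @param n_wolves,n_days,n_cameras counts.
#' @param fix_interval_min fix spacing, 10 or 30 minutes.
#' @param start_date first study date.
#' @param projection a [tangent_projection()] for the study area.
#' @param area_km side of the square study area, km.
#' @param tz_offset_hours fixed UTC offset of local time.
#' @param speed_mixture named numeric: `w_rest, mu_rest_log10,
#'   sd_rest_log10, w_travel, mu_travel_log10, sd_travel_log10`.
#' @param behavior_model list of logistic coefficients for P(travel):
#'   `intercept`, `night`, `category` (named offsets vs the event day),
#'   `night_by_category`, `ranef_intercept_sd`; or NULL.
#' @param speed_model list of linear coefficients on log10 travel speed:
#'   `intercept`, `night`, `category`, `ranef_intercept_sd`,
#'   `ranef_night_sd` (residual SD is `sd_travel_log10`); or NULL.
#' @param event_rate expected snowfall events per camera-winter.
#' @param accumulation_range_cm event accumulation range (min, max), cm.
#' @param depth_noise_cm depth measurement resolution, cm (0 = exact,
#'   drift-free series).
#' @param shared_event_prob probability an event date is drawn from the
#'   season-wide shared pool rather than being camera-local.
#' @param event_threshold_cm event definition used downstream (validated
#'   against `accumulation_range_cm`).
#' @param seed integer master seed; module streams are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_wolves = 17, n_days = 60, fix_interval_min = 30,
                       start_date = as.Date("2013-01-05"),
                       projection = tangent_projection(),
                       area_km = 90, tz_offset_hours = -7,
                       speed_mixture = c(w_rest = 0.67, mu_rest_log10 = -0.3,
                                         sd_rest_log10 = 0.45, w_travel = 0.33,
                                         mu_travel_log10 = 1.3, sd_travel_log10 = 0.35),
                       behavior_model = .default_behavior_model(),
                       speed_model = .default_speed_model(),
                       n_cameras = 14, event_rate = 4,
                       accumulation_range_cm = c(5, 16), depth_noise_cm = 1,
                       shared_event_prob = 0.5, event_threshold_cm = 5,
                       seed = 42) {
  chk <- function(ok, field, why) {
    if (!ok) abort(sprintf("Invalid sim_config field '%s': %s", field, why))
  }
  chk(n_wolves >= 1, "n_wolves", "must be a positive count")
  chk(n_days >= 7, "n_days", "must be at least 7")
  chk(n_cameras >= 1, "n_cameras", "must be a positive count")
  chk(fix_interval_min %in% c(10, 30), "fix_interval_min", "must be 10 or 30")
  chk(event_rate >= 0, "event_rate", "must be non-negative")
  chk(length(accumulation_range_cm) == 2 &&
        accumulation_range_cm[1] <= accumulation_range_cm[2],
      "accumulation_range_cm", "must be (min, max) with min <= max")
  chk(accumulation_range_cm[1] >= event_threshold_cm,
      "accumulation_range_cm", "minimum must be >= event_threshold_cm")
  chk(depth_noise_cm >= 0, "depth_noise_cm", "must be non-negative")
  chk(shared_event_prob >= 0 && shared_event_prob <= 1,
      "shared_event_prob", "must be in [0, 1]")
  mx <- speed_mixture
  chk(all(c("w_rest", "mu_rest_log10", "sd_rest_log10", "w_travel",
            "mu_travel_log10", "sd_travel_log10") %in% names(mx)),
      "speed_mixture", "must name all six mixture parameters")
  chk(isTRUE(all.equal(unname(mx["w_rest"] + mx["w_travel"]), 1)),
      "speed_mixture", "mixture weights must sum to 1")
  chk(mx["sd_rest_log10"] > 0 && mx["sd_travel_log10"] > 0,
      "speed_mixture", "component SDs must be positive")
  structure(
    list(n_wolves = n_wolves, n_days = n_days,
         fix_interval_min = fix_interval_min, start_date = start_date,
         projection = projection, area_km = area_km,
         tz_offset_hours = tz_offset_hours,
         speed_mixture = mx, behavior_model = behavior_model,
         speed_model = speed_model, n_cameras = n_cameras,
         event_rate = event_rate,
         accumulation_range_cm = accumulation_range_cm,
         depth_noise_cm = depth_noise_cm,
         shared_event_prob = shared_event_prob,
         event_threshold_cm = event_threshold_cm, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.round_res <- function(x, res) if (res > 0) round(x / res) * res else x

#' Simulate per-camera daily snow-depth series
#'
#' Cameras are scattered uniformly over the study square; each records a
#' depth every day from deployment. Event days inject an accumulation
#' drawn uniformly from `accumulation_range_cm` (rounded to the depth
#' resolution); non-event days drift by small settling noise that stays
#' strictly below the event threshold. Event dates are per camera, each
#' drawn from a season-wide shared pool with probability
#' `shared_event_prob` (shared events are seen by several cameras) and
#' locally otherwise.
#'
#' @param config a [sim_config()].
#' @return list with `deployments` (camera metadata), `readings`
#'   (`camera_id,date,depth_cm`) and `events` (injected truth:
#'   `camera_id,date,accumulation_cm`).
#' @export
simulate_snow_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    n_cam <- config$n_cameras
    ids <- sprintf("C%02d", seq_len(n_cam))
    half <- config$area_km * 500 # half-side in meters
    e0 <- config$projection$origin_easting
    n0 <- config$projection$origin_northing
    east <- runif(n_cam, e0 - half, e0 + half)
    north <- runif(n_cam, n0 - half, n0 + half)
    geo <- plane_to_geographic(config$projection, east, north)
    dates <- config$start_date + seq_len(config$n_days) - 1
    eligible <- dates[-1] # first day has no 24-h accumulation
    res <- config$depth_noise_cm
    pool_n <- max(1L, rpois(1, config$event_rate))
    pool <- sort(sample(eligible, min(pool_n, length(eligible))))
    cam_events <- vector("list", n_cam)
    readings <- vector("list", n_cam)
    init_depth <- .round_res(runif(n_cam, 30, 60), max(res, 1))
    for (k in seq_len(n_cam)) {
      n_ev <- min(rpois(1, config$event_rate), length(eligible))
      ev_dates <- as.Date(integer(0), origin = "1970-01-01")
      if (n_ev > 0) {
        n_shared <- min(rbinom(1, n_ev, config$shared_event_prob), length(pool))
        shared <- if (n_shared > 0) sample(pool, n_shared) else pool[0]
        remaining <- setdiff(eligible, shared)
        n_local <- min(n_ev - n_shared, length(remaining))
        local <- if (n_local > 0) {
          as.Date(sample(as.integer(remaining), n_local), origin = "1970-01-01")
        } else shared[0]
        ev_dates <- sort(unique(c(shared, local)))
      }
      delta <- rep(0, config$n_days)
      if (config$n_days > 1 && res > 0) {
        drift <- .round_res(rnorm(config$n_days - 1, -0.15, 0.7 * res), res)
        drift <- pmin(pmax(drift, -3 * res),
                      config$accumulation_range_cm[1] - res)
        delta[-1] <- drift
      }
      is_ev <- dates %in% ev_dates
      acc_ev <- .round_res(runif(sum(is_ev), config$accumulation_range_cm[1],
                                 config$accumulation_range_cm[2]), max(res, 1))
      delta[is_ev] <- acc_ev
      depth <- pmax(init_depth[k] + cumsum(delta) - delta[1], 0)
      readings[[k]] <- tibble::tibble(camera_id = ids[k], date = dates,
                                      depth_cm = depth)
      cam_events[[k]] <- tibble::tibble(camera_id = ids[k], date = dates[is_ev],
                                        accumulation_cm = acc_ev)
    }
    list(
      deployments = tibble::tibble(
        camera_id = ids, easting = east, northing = north,
        lat = geo$lat, lon = geo$lon,
        deploy_date = config$start_date, initial_depth_cm = init_depth
      ),
      readings = bind_rows(readings),
      events = bind_rows(cam_events)
    )
  })
}

.effect_lookup <- function(category, coefs) {
  # unassigned (outside any event window) days behave like controls
  key <- ifelse(category %in% names(coefs), category,
                ifelse(category == "day_of_snowfall", "day_of_snowfall", "control"))
  ifelse(key == "day_of_snowfall", 0, unname(coefs[key]))
}

#' Simulate wolf GPS tracks over a snow-series landscape
#'
#' Each wolf holds a home range in the study square and moves by a
#' persistent-heading random walk. At every fix interval a rest/travel
#' state is drawn with P(travel) from the logistic `behavior_model`
#' (night, snowfall category of the nearest camera's events, per-wolf
#' random intercept); travel speeds follow the log10-linear
#' `speed_model`, rest speeds the slow mixture component. Day/night truth
#' comes from the NOAA solar calculator at the study origin.
#'
#' @param config a [sim_config()].
#' @param snow output of [simulate_snow_series()] (same config).
#' @return list with `fixes` (telemetry tibble), `truth` (per-fix state,
#'   night flag, category, nearest camera, P(travel)) and `ranefs`
#'   (per-wolf random effects).
#' @export
simulate_wolf_tracks <- function(config, snow) {
  stopifnot(inherits(config, "sim_config"))
  mx <- config$speed_mixture
  bm <- config$behavior_model
  sm <- config$speed_model
  dt_min <- config$fix_interval_min
  tz_s <- config$tz_offset_hours * 3600
  dates <- config$start_date + seq_len(config$n_days) - 1
  # category truth per camera-day from each camera's own event dates
  cam_days <- tidyr::expand_grid(wolf_id = unique(snow$deployments$camera_id),
                                 camera_day = dates)
  cam_cats <- assign_snowfall_categories(
    cam_days, rename(snow$events, wolf_id = "camera_id", camera_day = "date"))
  cat_map <- split(setNames(cam_cats$snowfall_category,
                            as.character(cam_cats$camera_day)),
                   cam_cats$wolf_id)
  st <- sun_times(dates, config$projection$origin_lat,
                  config$projection$origin_lon, config$tz_offset_hours)
  sunrise <- setNames(as.numeric(st$sunrise), as.character(dates))
  sunset <- setNames(as.numeric(st$sunset), as.character(dates))
  # fix grid in UTC: local midnight of day 1 through local end of last day
  t0 <- as.numeric(as.POSIXct(paste(format(config$start_date), "00:00:00"),
                              tz = "UTC")) - tz_s
  times <- t0 + seq(0, config$n_days * 86400 - dt_min * 60, by = dt_min * 60)
  ts <- as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
  cam_day <- assign_camera_day(ts, config$tz_offset_hours)
  local_date <- as.Date(floor((times + tz_s) / 86400), origin = "1970-01-01")
  night <- !(times >= sunrise[as.character(local_date)] &
               times < sunset[as.character(local_date)])
  half <- config$area_km * 500
  e0 <- config$projection$origin_easting
  n0 <- config$projection$origin_northing
  day_index <- split(seq_along(times), cam_day)
  withr::with_seed(config$seed + 2L, {
    homes_e <- runif(config$n_wolves, e0 - 0.7 * half, e0 + 0.7 * half)
    homes_n <- runif(config$n_wolves, n0 - 0.7 * half, n0 + 0.7 * half)
    ranefs <- tibble::tibble(
      wolf_id = sprintf("W%02d", seq_len(config$n_wolves)),
      b_travel = rnorm(config$n_wolves, 0,
                       if (is.null(bm)) 0 else bm$ranef_intercept_sd),
      b_speed = rnorm(config$n_wolves, 0,
                      if (is.null(sm)) 0 else sm$ranef_intercept_sd),
      b_speed_night = rnorm(config$n_wolves, 0,
                            if (is.null(sm)) 0 else sm$ranef_night_sd)
    )
    fixes <- vector("list", config$n_wolves)
    truth <- vector("list", config$n_wolves)
    for (w in seq_len(config$n_wolves)) {
      pos <- c(homes_e[w], homes_n[w])
      heading <- runif(1, 0, 2 * pi)
      n_fix <- length(times)
      E <- numeric(n_fix); N <- numeric(n_fix)
      state <- character(n_fix); categ <- character(n_fix)
      cam_of <- character(n_fix); p_tr <- numeric(n_fix)
      for (d in names(day_index)) {
        idx <- day_index[[d]]
        dists <- sqrt((snow$deployments$easting - pos[1])^2 +
                        (snow$deployments$northing - pos[2])^2)
        cam <- snow$deployments$camera_id[which.min(dists)]
        cat_d <- unname(cat_map[[cam]][d])
        if (is.na(cat_d)) cat_d <- "unassigned"
        nt <- night[idx]
        if (is.null(bm)) {
          p <- rep(unname(mx["w_travel"]), length(idx))
        } else {
          eta <- bm$intercept + bm$night * nt +
            .effect_lookup(cat_d, bm$category) +
            nt * .effect_lookup(cat_d, bm$night_by_category) +
            ranefs$b_travel[w]
          p <- plogis(eta)
        }
        s <- rbinom(length(idx), 1, p) == 1
        if (is.null(sm)) {
          mu_t <- rep(unname(mx["mu_travel_log10"]), length(idx))
        } else {
          mu_t <- sm$intercept + sm$night * nt +
            .effect_lookup(cat_d, sm$category) +
            ranefs$b_speed[w] + nt * ranefs$b_speed_night[w]
        }
        logsp <- ifelse(s,
                        rnorm(length(idx), mu_t, mx["sd_travel_log10"]),
                        rnorm(length(idx), mx["mu_rest_log10"], mx["sd_rest_log10"]))
        speed <- 10^logsp
        # persistent heading while travelling, diffuse while resting;
        # re-aim at the home range when the walk strays
        turn <- rnorm(length(idx), 0, ifelse(s, 0.35, 2.0))
        for (j in seq_along(idx)) {
          if (sqrt(sum((pos - c(homes_e[w], homes_n[w]))^2)) > 12000) {
            heading <- atan2(homes_n[w] - pos[2], homes_e[w] - pos[1]) +
              rnorm(1, 0, 0.3)
          } else {
            heading <- heading + turn[j]
          }
          step_m <- speed[j] * dt_min
          pos <- pos + step_m * c(cos(heading), sin(heading))
          E[idx[j]] <- pos[1]; N[idx[j]] <- pos[2]
        }
        state[idx] <- ifelse(s, "travel", "rest")
        categ[idx] <- cat_d
        cam_of[idx] <- cam
        p_tr[idx] <- p
      }
      geo <- plane_to_geographic(config$projection, E, N)
      fixes[[w]] <- tibble::tibble(
        wolf_id = ranefs$wolf_id[w], timestamp = ts,
        easting = E, northing = N, lat = geo$lat, lon = geo$lon
      )
      truth[[w]] <- tibble::tibble(
        wolf_id = ranefs$wolf_id[w], timestamp = ts, camera_day = cam_day,
        state = state, night = night, snowfall_category = categ,
        camera_id = cam_of, p_travel = p_tr
      )
    }
    list(fixes = bind_rows(fixes), truth = bind_rows(truth), ranefs = ranefs)
  })
}

#' Simulate a complete dataset (cameras + tracks)
#' @param config a [sim_config()].
#' @return list with `snow` ([simulate_snow_series()] output) and
#'   `tracks` ([simulate_wolf_tracks()] output).
#' @export
simulate_dataset <- function(config) {
  snow <- simulate_snow_series(config)
  tracks <- simulate_wolf_tracks(config, snow)
  list(snow = snow, tracks = tracks)
}

#' Write a simulated dataset as CSV fixtures
#'
#' Emits `telemetry.csv`, `camera_deployments.csv`, `camera_depths.csv`,
#' `truth_states.csv`, `truth_ranefs.csv` and a column-documenting
#' `README.md` into `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fixes(sim$tracks$fixes, file.path(dir, "telemetry.csv"))
  dep <- sim$snow$deployments
  dep$deploy_date <- format(dep$deploy_date)
  write.csv(dep, file.path(dir, "camera_deployments.csv"),
            row.names = FALSE, quote = FALSE)
  rd <- sim$snow$readings
  rd$date <- format(rd$date)
  write.csv(rd, file.path(dir, "camera_depths.csv"),
            row.names = FALSE, quote = FALSE)
  tr <- sim$tracks$truth
  tr$timestamp <- strftime(tr$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tr$camera_day <- format(tr$camera_day)
  write.csv(tr, file.path(dir, "truth_states.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(sim$tracks$ranefs, file.path(dir, "truth_ranefs.csv"),
            row.names = FALSE, quote = FALSE)
  writeLines(c(
    "# Synthetic wolf/snow fixtures",
    "",
    "- telemetry.csv: wolf_id, timestamp (ISO-8601 UTC), easting/northing (m), lat/lon (deg)",
    "- camera_deployments.csv: camera_id, easting/northing (m), lat/lon (deg), deploy_date, initial_depth_cm",
    "- camera_depths.csv: camera_id, date, depth_cm (daily noon reading)",
    "- truth_states.csv: generating rest/travel state, night flag, snowfall category,",
    "  nearest camera and P(travel) for every fix (for recovery tests)",
    "- truth_ranefs.csv: per-wolf random effects used by the generator"
  ), file.path(dir, "README.md"))
  invisible(dir)
}
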