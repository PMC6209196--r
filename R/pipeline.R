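# End-to-end orchestration: simulate (or read) -> thin -> steps ->
# segment -> snow events -> categories/controls -> mixed-model selection
# -> bootstrap CIs -> summary tables, reproducible under one seed.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] to generate inputs, or NULL to read them
#'   from `telemetry_path` / `deployments_path` / `depths_path`.
#' @param telemetry_path,deployments_path,depths_path input CSVs (ignored
#'   when `sim` is given).
#' @param out_dir optional directory for CSV outputs and fixtures.
#' @param target_interval_min thinning grid, minutes.
#' @param interval_band acceptable step interval, minutes.
#' @param tz_offset_hours fixed UTC offset of study local time.
#' @param cutoff `"auto"` to fit the mixture and use the density
#'   intersection, or a fixed cutoff in m/min.
#' @param event_threshold_cm snowfall-event threshold, cm per 24 h.
#' @param n_controls control dates per wolf.
#' @param n_boot parametric-bootstrap simulations for the selected models
#'   (0 skips the bootstrap).
#' @param parsimony_window AIC window for [select_best()].
#' @param seed master seed for control sampling and the bootstrap.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), telemetry_path = NULL,
                       deployments_path = NULL, depths_path = NULL,
                       out_dir = NULL, target_interval_min = 30,
                       interval_band = c(19.75, 40.92), tz_offset_hours = -7,
                       cutoff = "auto", event_threshold_cm = 5,
                       n_controls = 3, n_boot = 0, parsimony_window = 4,
                       seed = 1) {
  if (is.null(sim) &&
      (is.null(telemetry_path) || is.null(deployments_path) || is.null(depths_path))) {
    missing <- c("telemetry_path", "deployments_path", "depths_path")[c(
      is.null(telemetry_path), is.null(deployments_path), is.null(depths_path))]
    abort(paste0("No simulation requested and missing input path(s): ",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(sim = sim, telemetry_path = telemetry_path,
         deployments_path = deployments_path, depths_path = depths_path,
         out_dir = out_dir, target_interval_min = target_interval_min,
         interval_band = interval_band, tz_offset_hours = tz_offset_hours,
         cutoff = cutoff, event_threshold_cm = event_threshold_cm,
         n_controls = n_controls, n_boot = n_boot,
         parsimony_window = parsimony_window, seed = as.integer(seed)),
    class = "run_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full pipeline
#'
#' Executes every stage in order and returns the intermediate tables, the
#' two 10-model selection tables, the selected models with (optionally
#' bootstrapped) coefficients, and descriptive per-category summaries.
#' When `config$sim` is given the synthetic fixtures are written to disk
#' (in `out_dir` or a temporary directory) and read back through the
#' package readers, so a simulated run exercises the same input path as a
#' real one.
#'
#' @param config a [run_config()].
#' @return A list of class `wolfsnow_run`; see Details in the vignette.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  config_in <- config # hash the configuration as supplied, not the temp paths
  io_dir <- config$out_dir %||% tempfile("wolfsnow_run_")
  if (!is.null(config$sim)) {
    .stage("simulate", {
      sim <- simulate_dataset(config$sim)
      write_synthetic_dataset(sim, io_dir)
      config$telemetry_path <- file.path(io_dir, "telemetry.csv")
      config$deployments_path <- file.path(io_dir, "camera_deployments.csv")
      config$depths_path <- file.path(io_dir, "camera_depths.csv")
    })
  }
  fixes <- .stage("read_telemetry", read_fixes(config$telemetry_path))
  deployments <- .stage("read_cameras", read_deployments(config$deployments_path))
  depths <- .stage("read_cameras", read_depths(config$depths_path))

  fixes <- .stage("thin", thin_to_interval(fixes, config$target_interval_min))
  steps <- .stage("steps", compute_steps(fixes, config$interval_band,
                                         config$tz_offset_hours))
  centroids <- .stage("centroids", daily_centroids(fixes, config$tz_offset_hours))
  steps <- .stage("time_of_day",
                  label_time_of_day(steps, centroids, config$tz_offset_hours))

  seg <- .stage("segment", {
    ls <- log10_speed(steps$speed_mpm)
    if (identical(config$cutoff, "auto")) {
      mixture <- fit_mixture(ls)
      cutoff <- find_intersection(mixture)
    } else {
      mixture <- NULL
      cutoff <- structure(list(value_log10 = log10(config$cutoff),
                               value_mpm = config$cutoff),
                          class = "speed_cutoff")
    }
    list(mixture = mixture, cutoff = cutoff,
         plot = if (!is.null(mixture)) plot_speed_mixture(ls, mixture, cutoff),
         steps = classify_steps(steps, cutoff))
  })
  steps <- seg$steps

  snow_daily <- .stage("snow", build_snow_daily(depths, deployments,
                                                config$event_threshold_cm))
  wolf_day <- .stage("snow_join", join_wolf_day(centroids, snow_daily, deployments))
  events <- filter(wolf_day, .data$is_event %in% TRUE) %>%
    select("wolf_id", "camera_day")

  wolf_days <- distinct(select(steps, "wolf_id", "camera_day"))
  categories <- .stage("categories", assign_snowfall_categories(wolf_days, events))
  controls <- .stage("controls", sample_controls(wolf_days, events,
                                                 config$n_controls, config$seed))
  analysis <- .stage("dataset",
                     build_analysis_dataset(steps, categories, controls, wolf_day))

  speed_fits <- .stage("fit_speed", fit_candidates(analysis, "log10_speed"))
  travel_fits <- .stage("fit_travel", fit_candidates(analysis, "behavior"))
  speed_table <- selection_table(speed_fits)
  travel_table <- selection_table(travel_fits)
  speed_best <- select_best(speed_table, config$parsimony_window)
  travel_best <- select_best(travel_table, config$parsimony_window)

  boot <- list(speed = NULL, travel = NULL)
  if (config$n_boot > 0) {
    boot$speed <- .stage("bootstrap", parametric_bootstrap_ci(
      speed_fits[[speed_best$name]], n_sim = config$n_boot,
      seed = config$seed + 10L))
    boot$travel <- .stage("bootstrap", parametric_bootstrap_ci(
      travel_fits[[travel_best$name]], n_sim = config$n_boot,
      seed = config$seed + 11L))
  }

  summaries <- .stage("summaries", .summaries(analysis, steps))

  run <- structure(list(
    config = config,
    steps = steps, centroids = centroids, snow_daily = snow_daily,
    wolf_day = wolf_day, analysis = analysis,
    mixture = seg$mixture, cutoff = seg$cutoff, mixture_plot = seg$plot,
    speed_fits = speed_fits, travel_fits = travel_fits,
    speed_table = speed_table, travel_table = travel_table,
    speed_best = speed_best, travel_best = travel_best,
    bootstrap = boot, summaries = summaries,
    manifest = list(
      package_version = as.character(utils::packageVersion("wolfsnow")),
      r_version = R.version.string,
      config_hash = rlang::hash(config_in),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "wolfsnow_run")
  if (!is.null(config$out_dir)) .write_run(run, config$out_dir)
  run
}

.summaries <- function(analysis, steps) {
  by_cat_tod <- analysis %>%
    group_by(.data$snowfall_category, .data$time_of_day) %>%
    summarise(
      n_steps = dplyr::n(),
      travel_proportion = mean(.data$behavior == "travel"),
      mean_travel_speed_mpm = mean(.data$speed_mpm[.data$behavior == "travel"]),
      sd_travel_speed_mpm = sd(.data$speed_mpm[.data$behavior == "travel"]),
      .groups = "drop"
    )
  daily_km <- analysis %>%
    group_by(.data$wolf_id, .data$camera_day, .data$snowfall_category) %>%
    summarise(km = sum(.data$distance_m) / 1000, .groups = "drop") %>%
    group_by(.data$snowfall_category) %>%
    summarise(mean_km_per_day = mean(.data$km), sd_km_per_day = sd(.data$km),
              .groups = "drop")
  list(by_category_time_of_day = by_cat_tod, daily_distance = daily_km)
}

.write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$speed_table, file.path(dir, "selection_speed.csv"), row.names = FALSE)
  write.csv(run$travel_table, file.path(dir, "selection_travel.csv"), row.names = FALSE)
  an <- run$analysis
  an$camera_day <- format(an$camera_day)
  an$t_start <- strftime(an$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  an$t_end <- strftime(an$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(an, file.path(dir, "analysis_dataset.csv"), row.names = FALSE)
  write.csv(run$summaries$by_category_time_of_day,
            file.path(dir, "summary_category_timeofday.csv"), row.names = FALSE)
  write.csv(run$summaries$daily_distance,
            file.path(dir, "summary_daily_distance.csv"), row.names = FALSE)
  if (!is.null(run$bootstrap$speed)) {
    write.csv(run$bootstrap$speed, file.path(dir, "coefficients_speed.csv"),
              row.names = FALSE)
    write.csv(run$bootstrap$travel, file.path(dir, "coefficients_travel.csv"),
              row.names = FALSE)
  }
  writeLines(c(
    paste0("package_version: ", run$manifest$package_version),
    paste0("r_version: ", run$manifest$r_version),
    paste0("config_hash: ", run$manifest$config_hash)
  ), file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.wolfsnow_run <- function(x, ...) {
  cat("wolfsnow pipeline run\n")
  cat(sprintf("  %d analysis steps, %d wolves\n",
              nrow(x$analysis), length(unique(x$analysis$wolf_id))))
  if (!is.null(x$cutoff)) {
    cat(sprintf("  rest/travel cutoff: %.3f m/min\n", x$cutoff$value_mpm))
  }
  cat(sprintf("  best speed model:  %s (K = %d)\n",
              x$speed_best$formula_text, x$speed_best$K))
  cat(sprintf("  best travel model: %s (K = %d)\n",
              x$travel_best$formula_text, x$travel_best$K))
  invisible(x)
}
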