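test_that("config validation names the offending field", {
  expect_error(sim_config(n_wolves = 0), "n_wolves")
  expect_error(sim_config(n_days = 3), "n_days")
  expect_error(sim_config(accumulation_range_cm = c(10, 5)), "accumulation_range_cm")
  expect_error(sim_config(accumulation_range_cm = c(2, 10)), "accumulation_range_cm")
  expect_error(sim_config(fix_interval_min = 15), "fix_interval_min")
  bad_mx <- c(w_rest = 0.6, mu_rest_log10 = -0.3, sd_rest_log10 = 0.45,
              w_travel = 0.3, mu_travel_log10 = 1.3, sd_travel_log10 = 0.35)
  expect_error(sim_config(speed_mixture = bad_mx), "sum to 1")
})

test_that("zero event rate and zero depth noise give constant series with no events", {
  cfg <- sim_config(n_wolves = 1, n_days = 10, n_cameras = 3,
                    event_rate = 0, depth_noise_cm = 0, seed = 1)
  snow <- simulate_snow_series(cfg)
  per_cam <- split(snow$readings$depth_cm, snow$readings$camera_id)
  for (d in per_cam) expect_equal(length(unique(d)), 1)
  sd <- build_snow_daily(snow$readings, snow$deployments)
  expect_false(any(sd$is_event, na.rm = TRUE))
  expect_equal(nrow(snow$events), 0)
})

test_that("snow series are deterministic, complete, non-negative and localized", {
  cfg <- small_sim(seed = 14)
  a <- simulate_snow_series(cfg)
  b <- simulate_snow_series(cfg)
  expect_identical(a, b)
  expect_true(all(a$readings$depth_cm >= 0))
  # every camera has a reading for every date
  tab <- table(a$readings$camera_id)
  expect_true(all(tab == cfg$n_days))
  # detected events equal injected events
  sd <- build_snow_daily(a$readings, a$deployments)
  det <- sd[sd$is_event %in% TRUE, c("camera_id", "date")]
  expect_equal(nrow(det), nrow(a$events))
  expect_setequal(paste(det$camera_id, det$date),
                  paste(a$events$camera_id, a$events$date))
})

test_that("mean detected events per camera matches the configured rate", {
  # Monte-Carlo over replicate seeds at 4 expected events/camera, 60 days
  n_rep <- 400
  counts <- vapply(seq_len(n_rep), function(s) {
    cfg <- sim_config(n_wolves = 1, n_days = 60, n_cameras = 2,
                      event_rate = 4, seed = 1000 + s)
    snow <- simulate_snow_series(cfg)
    sd <- build_snow_daily(snow$readings, snow$deployments)
    sum(sd$is_event, na.rm = TRUE) / cfg$n_cameras
  }, numeric(1))
  mc_se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 4), 3 * mc_se)
})

test_that("fix timestamps sit on the configured grid and runs are reproducible", {
  cfg <- sim_config(n_wolves = 2, n_days = 8, n_cameras = 3,
                    fix_interval_min = 10, seed = 3)
  sim <- simulate_dataset(cfg)
  by_wolf <- split(sim$tracks$fixes$timestamp, sim$tracks$fixes$wolf_id)
  for (tsw in by_wolf) {
    expect_true(all(diff(as.numeric(tsw)) == 600))
  }
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$tracks$fixes, sim2$tracks$fixes)

  # byte-identical files from the same seed + config
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(sim, d1)
  write_synthetic_dataset(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("camera regeneration does not perturb the track RNG stream", {
  cfg <- sim_config(n_wolves = 2, n_days = 8, n_cameras = 3, seed = 9)
  snow1 <- simulate_snow_series(cfg)
  snow1b <- simulate_snow_series(cfg) # regenerate cameras in between
  tr1 <- simulate_wolf_tracks(cfg, snow1)
  tr2 <- simulate_wolf_tracks(cfg, snow1b)
  expect_identical(tr1$fixes, tr2$fixes)
})

test_that("generated files round-trip through the package readers", {
  sim <- simulate_dataset(small_sim(seed = 8))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(sim, dir)
  fx <- suppressMessages(read_fixes(file.path(dir, "telemetry.csv")))
  expect_equal(nrow(fx), nrow(sim$tracks$fixes))
  expect_equal(fx$timestamp, sim$tracks$fixes$timestamp)
  expect_equal(fx$easting, sim$tracks$fixes$easting, tolerance = 1e-9)
  dep <- read_deployments(file.path(dir, "camera_deployments.csv"))
  expect_equal(dep$camera_id, sim$snow$deployments$camera_id)
  expect_equal(dep$deploy_date, sim$snow$deployments$deploy_date)
  rd <- read_depths(file.path(dir, "camera_depths.csv"))
  expect_equal(rd$depth_cm, sim$snow$readings$depth_cm, tolerance = 1e-9)
})

test_that("null category effects equalize travel across event and control days", {
  bm <- list(
    intercept = -0.5, night = 0,
    category = c(control = 0, two_before = 0, one_before = 0,
                 one_after = 0, two_after = 0, three_after = 0),
    night_by_category = c(control = 0, two_before = 0, one_before = 0,
                          one_after = 0, two_after = 0, three_after = 0),
    ranef_intercept_sd = 0
  )
  cfg <- sim_config(n_wolves = 8, n_days = 40, n_cameras = 4,
                    behavior_model = bm, seed = 77)
  sim <- simulate_dataset(cfg)
  tr <- sim$tracks$truth
  p_event <- mean(tr$state[tr$snowfall_category == "day_of_snowfall"] == "travel")
  p_out <- mean(tr$state[tr$snowfall_category == "unassigned"] == "travel")
  n1 <- sum(tr$snowfall_category == "day_of_snowfall")
  n2 <- sum(tr$snowfall_category == "unassigned")
  mc <- 3 * sqrt(0.25 / n1 + 0.25 / n2)
  expect_lt(abs(p_event - p_out), mc)
})

test_that("travel fraction matches the inverse-logit of the linear predictor", {
  sim <- simulate_dataset(small_sim(seed = 19))
  tr <- sim$tracks$truth
  expected <- mean(tr$p_travel)
  observed <- mean(tr$state == "travel")
  mc_se <- sqrt(sum(tr$p_travel * (1 - tr$p_travel))) / nrow(tr)
  expect_lt(abs(observed - expected), 3 * mc_se)
})

test_that("a positive night speed coefficient raises night travel speeds", {
  sim <- simulate_dataset(small_sim(seed = 23))
  tr <- sim$tracks$truth
  thin <- sim$tracks$fixes
  st <- suppressMessages(compute_steps(thin))
  key <- match(paste(st$wolf_id, st$t_end), paste(tr$wolf_id, tr$timestamp))
  st$state <- tr$state[key]
  st$night <- tr$night[key]
  trav <- st[st$state == "travel", ]
  m_night <- mean(log10(trav$speed_mpm[trav$night]))
  m_day <- mean(log10(trav$speed_mpm[!trav$night]))
  expect_gt(m_night, m_day)
})
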