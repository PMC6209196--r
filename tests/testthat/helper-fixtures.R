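# Shared fixture builders. Everything is generated in code; no files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A hand-sized fix table: one wolf unless stated, projected meters plus
# tangent-plane geographic coordinates.
make_fixes <- function(times, easting, northing, wolf_id = "W01",
                       proj = tangent_projection()) {
  geo <- plane_to_geographic(proj, easting, northing)
  tibble::tibble(
    wolf_id = wolf_id, timestamp = utc(times),
    easting = easting, northing = northing, lat = geo$lat, lon = geo$lon
  )
}

# Regular 30-min fix track of n fixes starting at `start`, stationary at
# (e0, n0) unless offsets are supplied.
make_track <- function(n, start = "2013-01-10 00:00:00", wolf_id = "W01",
                       e0 = 500000, n0 = 6250000, de = rep(0, n), dn = rep(0, n)) {
  make_fixes(seq(utc(start), by = 1800, length.out = n),
             easting = e0 + cumsum(de), northing = n0 + cumsum(dn),
             wolf_id = wolf_id)
}

# Small, fast simulation config for pipeline-level tests.
small_sim <- function(seed = 11, ...) {
  sim_config(n_wolves = 5, n_days = 24, n_cameras = 5, seed = seed, ...)
}

# Config whose speeds come straight from the mixture (no covariate
# structure), for parameter-recovery checks.
mixture_only_sim <- function(seed = 21, n_wolves = 17, n_days = 62, ...) {
  sim_config(n_wolves = n_wolves, n_days = n_days, n_cameras = 6,
             behavior_model = NULL, speed_model = NULL, seed = seed, ...)
}

# Simulated balanced two-level dataset for direct model fitting, bypassing
# the telemetry stages: analysis rows with known generating coefficients.
make_glmm_data <- function(n_wolves = 10, n_per = 150, intercept = -0.5,
                           night_beta = 0.6, ranef_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    wolf <- sprintf("W%02d", rep(seq_len(n_wolves), each = n_per))
    night <- rbinom(n_wolves * n_per, 1, 0.5)
    b <- rnorm(n_wolves, 0, ranef_sd)
    eta <- intercept + night_beta * night + b[rep(seq_len(n_wolves), each = n_per)]
    tibble::tibble(
      wolf_id = wolf,
      time_of_day = ifelse(night == 1, "night", "day"),
      snowfall_category = "day_of_snowfall",
      behavior = ifelse(rbinom(length(eta), 1, plogis(eta)) == 1, "travel", "rest"),
      snow_depth_cm = 40
    )
  })
}

make_lmm_data <- function(n_wolves = 10, n_per = 150, intercept = 1.1,
                          night_beta = 0.1, ranef_sd = 0.15,
                          ranef_night_sd = 0.08, resid_sd = 0.35, seed = 1) {
  withr::with_seed(seed, {
    wolf_idx <- rep(seq_len(n_wolves), each = n_per)
    night <- rbinom(n_wolves * n_per, 1, 0.5)
    b0 <- rnorm(n_wolves, 0, ranef_sd)
    b1 <- rnorm(n_wolves, 0, ranef_night_sd)
    mu <- intercept + night_beta * night + b0[wolf_idx] + b1[wolf_idx] * night
    tibble::tibble(
      wolf_id = sprintf("W%02d", wolf_idx),
      time_of_day = ifelse(night == 1, "night", "day"),
      snowfall_category = "day_of_snowfall",
      behavior = "travel",
      log10_speed = mu + rnorm(length(mu), 0, resid_sd),
      snow_depth_cm = 40
    )
  })
}

# Grid-scan oracle for the mixture density intersection: coarse sign-change
# localization followed by a 1e-6-step scan, independent of the quadratic
# solver under test.
grid_intersection <- function(mix, coarse = 1e-3, fine = 1e-6) {
  f <- function(x) {
    log(mix$w1) + dnorm(x, mix$mu1, mix$sd1, log = TRUE) -
      log(mix$w2) - dnorm(x, mix$mu2, mix$sd2, log = TRUE)
  }
  xs <- seq(mix$mu1, mix$mu2, by = coarse)
  v <- f(xs)
  sc <- which(diff(sign(v)) != 0)
  if (length(sc) == 0) return(NA_real_)
  lo <- xs[sc[1]]
  xs2 <- seq(lo - coarse, lo + 2 * coarse, by = fine)
  v2 <- abs(f(xs2))
  xs2[which.min(v2)]
}
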