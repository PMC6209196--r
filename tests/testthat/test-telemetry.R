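test_that("read_fixes parses well-formed files and rejects malformed ones", {
  fx <- make_track(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixes(fx, path)
  got <- suppressMessages(read_fixes(path))
  expect_equal(nrow(got), 3)
  expect_equal(got$timestamp, fx$timestamp)
  expect_equal(got$easting, fx$easting, tolerance = 1e-8)

  # duplicated row: one copy kept, with a warning
  dup <- fx[c(1, 1, 2, 3), ]
  write_fixes(dup, path)
  expect_warning(got2 <- suppressMessages(read_fixes(path)), "duplicate")
  expect_equal(nrow(got2), 3)

  # missing column named in the error
  broken <- read.csv(path)[, -4]
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_fixes(path), "northing")

  # unparseable timestamp reported with its row number
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixes(fx, path)
  raw <- readLines(path)
  raw[3] <- sub("2013-01-10T00:30:00Z", "not-a-time", raw[3])
  writeLines(raw, path)
  expect_error(read_fixes(path), "row 2")
})

test_that("thinning keeps the fix nearest each :00/:30 grid slot", {
  # ten-minute data: :00,:10,:20,:30,:40,:50,:00 -> :00,:30,:00
  t0 <- utc("2013-01-10 06:00:00")
  fx <- make_fixes(t0 + seq(0, 3600, by = 600), easting = 500000 + 0:6,
                   northing = rep(0, 7) + 6250000)
  thin <- thin_to_interval(fx, 30)
  expect_equal(thin$timestamp, t0 + c(0, 1800, 3600))

  # 30-min data pass through unchanged (idempotence)
  fx30 <- make_track(10)
  expect_equal(thin_to_interval(fx30, 30), fx30)
  expect_equal(thin_to_interval(thin_to_interval(fx, 30), 30), thin)
})

test_that("thinning matches brute-force nearest-grid assignment for every offset", {
  # single fix at each minute offset 0-29 past the hour: nearest slot wins,
  # an exact midpoint (offset 15) goes to the later slot
  base <- utc("2013-01-10 06:00:00")
  for (off in 0:29) {
    fx <- make_fixes(base + off * 60, easting = 500000, northing = 6250000)
    thin <- thin_to_interval(fx, 30)
    expected_slot <- if (off < 15) 0 else 1800
    slot_of <- floor(as.numeric(thin$timestamp - base, units = "secs") / 1800 + 0.5) * 1800
    expect_equal(slot_of, expected_slot, info = paste("offset", off))
  }
  # :14 and :16 compete for the :15 boundary: :14 -> :00 slot, :16 -> :30 slot
  fx <- make_fixes(base + c(14, 16) * 60, easting = c(0, 100) + 500000,
                   northing = c(0, 0) + 6250000)
  thin <- thin_to_interval(fx, 30)
  expect_equal(nrow(thin), 2)
})

test_that("steps carry Euclidean speed and drop out-of-band intervals", {
  fx <- make_track(3, de = c(0, 900, 900))
  st <- suppressMessages(compute_steps(fx))
  expect_equal(nrow(st), 2)
  expect_equal(st$speed_mpm, c(30, 30))

  # identical consecutive positions -> zero speed
  fx0 <- make_track(2)
  st0 <- suppressMessages(compute_steps(fx0))
  expect_equal(st0$speed_mpm, 0)

  # three collinear fixes 300 m apart -> two steps of 10 m/min
  fx3 <- make_track(3, dn = c(0, 300, 300))
  st3 <- suppressMessages(compute_steps(fx3))
  expect_equal(st3$speed_mpm, c(10, 10))

  # a gap outside the acceptance band yields no spanning step
  fx_gap <- make_fixes(utc("2013-01-10 00:00:00") + c(0, 1800, 9000),
                       easting = c(0, 100, 200) + 500000,
                       northing = rep(0, 3) + 6250000)
  st_gap <- suppressMessages(compute_steps(fx_gap))
  expect_equal(nrow(st_gap), 1)

  expect_warning(suppressMessages(compute_steps(make_track(1))), "single fix")
})

test_that("camera-day shifts fixes after local noon to the next date", {
  # local time = UTC - 7
  expect_equal(assign_camera_day(utc("2013-01-05 18:59:00"), -7), # 11:59 local
               as.Date("2013-01-05"))
  expect_equal(assign_camera_day(utc("2013-01-05 19:01:00"), -7), # 12:01 local
               as.Date("2013-01-06"))
  expect_equal(assign_camera_day(utc("2013-01-05 19:00:00"), -7), # exactly noon
               as.Date("2013-01-05"))
})

test_that("day/night classification follows NOAA sunrise and sunset", {
  # equator on an equinox: local solar noon at lon 0 is ~12:00 UTC
  noon <- utc("2013-03-20 12:00:00")
  midnight <- utc("2013-03-20 00:00:00")
  expect_equal(classify_time_of_day(noon, 0, 0, 0), "day")
  expect_equal(classify_time_of_day(midnight, 0, 0, 0), "night")

  # the study area in mid-January: 12:00 local is day, 03:00 local night
  expect_equal(classify_time_of_day(utc("2013-01-15 19:00:00"), 56.4, -111.1, -7),
               "day")
  expect_equal(classify_time_of_day(utc("2013-01-15 10:00:00"), 56.4, -111.1, -7),
               "night")
  # winter sunrise at 56.4 N falls mid-morning local time
  st <- sun_times(as.Date("2013-01-15"), 56.4, -111.1, -7)
  sunrise_local_h <- as.numeric(st$sunrise - utc("2013-01-15 00:00:00"),
                                units = "hours") - 7
  expect_gt(sunrise_local_h, 7.5)
  expect_lt(sunrise_local_h, 10)

  expect_error(classify_time_of_day(noon, 70, 0, 0), "66.5")
})

test_that("daily centroids average projected coordinates per wolf-day", {
  fx <- make_fixes(utc("2013-01-10 00:00:00") + c(0, 1800),
                   easting = c(0, 100) + 500000, northing = c(0, 0) + 6250000)
  ctr <- daily_centroids(fx)
  expect_equal(nrow(ctr), 1)
  expect_equal(ctr$easting, 500050)
  expect_equal(ctr$northing, 6250000)

  one <- daily_centroids(make_track(1))
  expect_equal(one$easting, 500000)
  expect_equal(one$n_fixes, 1)

  # 48 fixes symmetric about (500500, 6250500)
  ang <- seq(0, 2 * pi, length.out = 49)[-49]
  sym <- make_fixes(utc("2013-01-10 00:00:00") + seq_along(ang) * 60,
                    easting = 500500 + 200 * cos(ang),
                    northing = 6250500 + 200 * sin(ang))
  ctr_sym <- daily_centroids(sym)
  expect_equal(ctr_sym$easting, 500500, tolerance = 1e-9)
  expect_equal(ctr_sym$northing, 6250500, tolerance = 1e-9)
})

test_that("thinned conforming tracks yield ~30-min mean intervals and monotone camera-days", {
  sim <- simulate_dataset(small_sim(seed = 5))
  thin <- thin_to_interval(sim$tracks$fixes, 30)
  st <- suppressMessages(compute_steps(thin))
  expect_equal(mean(st$interval_min), 30, tolerance = 0.01)
  # steps per wolf = retained fixes - 1 (no gaps in synthetic data)
  n_fix <- table(thin$wolf_id)
  n_step <- table(st$wolf_id)
  expect_equal(as.integer(n_step), as.integer(n_fix) - 1L)
  for (w in unique(st$wolf_id)) {
    cd <- st$camera_day[st$wolf_id == w]
    expect_true(all(diff(as.integer(cd)) >= 0))
  }
})
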