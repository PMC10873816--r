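test_that("orientation_angle measures principal-axis tilt from vertical", {
  vert <- matrix(0, 41, 41); vert[6:36, 20:22] <- 1
  expect_equal(orientation_angle(vert), 0)
  horiz <- matrix(0, 41, 41); horiz[20:22, 6:36] <- 1
  expect_equal(orientation_angle(horiz), 90)
  # rasterized 45-degree bars, both tilts
  ccw <- matrix(0, 41, 41)
  cw <- matrix(0, 41, 41)
  for (i in 1:30) {
    ccw[5 + i, 5 + i] <- 1   # top of bar leans left: counterclockwise
    cw[36 - i, 5 + i] <- 1   # top leans right: clockwise
  }
  expect_equal(orientation_angle(ccw), 45, tolerance = 1)
  expect_equal(orientation_angle(cw), -45, tolerance = 1)
})

test_that("rotating a bar mask by +theta shifts its orientation by +theta", {
  angles <- c(-60, -30, 15, 30, 60)
  for (theta in angles) {
    mask <- matrix(0, 81, 81)
    a <- theta * pi / 180
    for (s in seq(-25, 25, by = 0.5)) {
      r <- 41 - round(s * cos(a))
      c <- 41 - round(s * sin(a))
      mask[r + (-1:1), c] <- 1
    }
    expect_equal(orientation_angle(mask), theta, tolerance = 2)
  }
})

test_that("degenerate masks are rejected", {
  expect_error(orientation_angle(matrix(0, 5, 5)), "no foreground")
  disc <- outer(1:41, 1:41, function(r, c) (r - 21)^2 + (c - 21)^2 <= 100)
  expect_error(orientation_angle(disc), "orientation undefined")
})

test_that("roll_angle follows the counterclockwise-from-x convention", {
  expect_equal(roll_angle(c(0, 0), c(2, 0)), 0)
  expect_equal(roll_angle(c(0, 0), c(0, 3)), 90)
  expect_equal(roll_angle(c(1, 1), c(0, 1)), 180)
  expect_error(roll_angle(c(1, 1), c(1, 1)), "marker on midline")
  # marker stepped by 30-degree increments on a synthetic dial
  steps <- seq(0, 150, by = 30)
  got <- vapply(steps, function(a) {
    roll_angle(c(0, 0), c(cos(a * pi / 180), sin(a * pi / 180)))
  }, numeric(1))
  expect_equal(got, steps, tolerance = 1e-9)
})

test_that("unwrapping applies the minimal-jump rule and inverts wrapping", {
  s <- angle_series(c(1, 2, 3), roll_deg = c(0, 170, -170))
  expect_equal(unwrap_series(s)$roll_deg, c(0, 170, 190))
  const <- angle_series(c(1, 2, 3), roll_deg = c(12, 12, 12))
  expect_equal(unwrap_series(const)$roll_deg, c(12, 12, 12))
})

test_that("wrap/unwrap round-trips 1000 simulated random walks exactly", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      n <- sample(3:12, 1)
      walk <- cumsum(c(runif(1, -180, 180), runif(n - 1, -179, 179)))
      wrapped <- walk - 360 * ceiling((walk - 180) / 360)
      s <- angle_series(seq_len(n), roll_deg = wrapped)
      expect_equal(unwrap_series(s)$roll_deg - unwrap_series(s)$roll_deg[1],
                   walk - walk[1], tolerance = 1e-9)
    }
  })
})

test_that("classification partitions twisting and resupination at 180 degrees", {
  expect_identical(as.character(classify_movement(0, 45)), "twisting")
  expect_identical(as.character(classify_movement(0, 180)), "resupination")
  expect_identical(as.character(classify_movement(0, 0)), character(0))
  expect_identical(as.character(classify_movement(30, 0)), "bending")
  for (r in seq(6, 360, by = 1)) {
    k <- classify_movement(0, r)
    expect_identical(sum(c("twisting", "resupination") %in% k), 1L,
                     info = paste("roll", r))
    expect_identical("resupination" %in% k, r >= 180)
  }
  # beyond 360: full cycles counted, remainder classified
  k <- classify_movement(0, 450)
  expect_true("resupination" %in% k)
  expect_identical(attr(k, "cycles"), 1L)
})

test_that("max_excursion reports magnitude and direction from the window start", {
  fruit <- angle_series(c(7, 14, 21, 28),
                        orientation_deg = c(67.5, 45, 45, 67.5))
  exc <- max_excursion(fruit, "orientation", window = c(7, 28))
  expect_equal(as.numeric(exc), 22.5)
  expect_identical(attr(exc, "direction"), "clockwise")
  const <- angle_series(1:4, orientation_deg = rep(10, 4))
  expect_equal(as.numeric(max_excursion(const, "orientation")), 0)
  ramp <- angle_series(1:5, orientation_deg = c(0, 5, 12, 20, 31))
  expect_equal(as.numeric(max_excursion(ramp, "orientation")), 31)
  # brute force over all t agrees
  expect_equal(as.numeric(max_excursion(ramp, "orientation")),
               max(abs(ramp$orientation_deg - ramp$orientation_deg[1])))
  expect_error(max_excursion(ramp, "orientation", window = c(0, 5)),
               "window not covered")
})

test_that("detect_events finds maximal monotone runs with classified kinds", {
  fruit <- angle_series(c(7, 14, 21, 28),
                        orientation_deg = c(67.5, 45, 45, 67.5))
  ev <- detect_events(fruit)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$kind, c("bending", "bending"))
  expect_equal(ev$start_day, c(7, 21))
  expect_equal(ev$end_day, c(14, 28))
  expect_equal(ev$magnitude_deg, c(22.5, 22.5))
  expect_equal(ev$direction, c("clockwise", "counterclockwise"))

  const <- angle_series(1:4, orientation_deg = rep(3, 4))
  expect_equal(nrow(detect_events(const)), 0)

  ramp <- angle_series(c(7, 14, 21), roll_deg = c(0, 90, 180), unwrapped = TRUE)
  ev2 <- detect_events(ramp)
  expect_equal(nrow(ev2), 1)
  expect_identical(ev2$kind, "resupination")
  expect_equal(ev2$magnitude_deg, 180)
  expect_equal(c(ev2$start_day, ev2$end_day), c(7, 21))
})

test_that("resupination onset is the first day cumulative roll reaches 180", {
  s <- angle_series(c(70, 77, 84, 91), roll_deg = c(0, 90, 180, 270),
                    unwrapped = TRUE)
  expect_equal(resupination_onset(s), 84)
  none <- angle_series(c(1, 2), roll_deg = c(0, 90), unwrapped = TRUE)
  expect_true(is.na(resupination_onset(none)))
})

test_that("movement logs round-trip through CSV", {
  fruit <- angle_series(c(7, 14, 21, 28),
                        orientation_deg = c(67.5, 45, 45, 67.5))
  ev <- detect_events(fruit)
  path <- withr::local_tempfile(fileext = ".csv")
  movement_log(ev, path)
  back <- read_movement_log(path)
  expect_equal(as.data.frame(back), as.data.frame(ev))
  # empty event list: header-only file
  movement_log(detect_events(angle_series(1:2, orientation_deg = c(1, 1))), path)
  expect_length(readLines(path), 1)
})

test_that("angle series CSV reader restores channels", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(day = c(7, 14), orientation_deg = c(10, 20),
                                  roll_deg = c(0, 45)), path)
  s <- read_angle_series(path)
  expect_s3_class(s, "angle_series")
  expect_equal(s$roll_deg, c(0, 45))
})

test_that("autoplot methods return ggplot objects", {
  fruit <- angle_series(c(7, 14, 21, 28),
                        orientation_deg = c(67.5, 45, 45, 67.5))
  expect_s3_class(ggplot2::autoplot(fruit), "ggplot")
  expect_s3_class(ggplot2::autoplot(detect_events(fruit)), "ggplot")
})
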