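#' Per-organ angle time series
#'
#' Holds the weekly protractor-style measurements for one organ: the in-plane
#' orientation of its long axis measured from the image vertical (y) axis,
#' and optionally the axial roll (azimuth of a fixed surface marker about the
#' organ midline). Angles are in degrees, counterclockwise-positive in image
#' coordinates (y up); the time axis is integer days (after germination for
#' roots, after pollination for fruits).
#'
#' @param days Strictly increasing integer days.
#' @param orientation_deg Orientation angles, same length as `days` (may be
#'   `NULL` when only roll was measured).
#' @param roll_deg Axial roll angles, same length as `days` (may be `NULL`).
#' @param unwrapped `TRUE` when `roll_deg` is cumulative rather than wrapped
#'   to `(-180, 180]`.
#' @param organ Organ identifier.
#' @return An object of class `angle_series` (also a tibble).
#' @seealso [unwrap_series()], [detect_events()], [max_excursion()]
#' @export
#' @examples
#' fruit <- angle_series(c(7, 14, 21, 28), orientation_deg = c(67.5, 45, 45, 67.5))
#' max_excursion(fruit, "orientation", window = c(7, 28))
angle_series <- function(days, orientation_deg = NULL, roll_deg = NULL,
                         unwrapped = FALSE, organ = "organ") {
  days <- as.numeric(days)
  if (length(days) < 1 || any(diff(days) <= 0)) {
    stop("days must be non-empty and strictly increasing")
  }
  for (ch in list(orientation_deg, roll_deg)) {
    if (!is.null(ch) && length(ch) != length(days)) {
      stop("angle channels must match the length of days")
    }
  }
  if (is.null(orientation_deg) && is.null(roll_deg)) {
    stop("at least one of orientation_deg / roll_deg is required")
  }
  if (!unwrapped && !is.null(roll_deg) &&
      any(roll_deg <= -180 | roll_deg > 180, na.rm = TRUE)) {
    stop("wrapped roll angles must lie in (-180, 180]")
  }
  out <- tibble::tibble(
    day = days,
    orientation_deg = if (is.null(orientation_deg)) NA_real_ else as.numeric(orientation_deg),
    roll_deg = if (is.null(roll_deg)) NA_real_ else as.numeric(roll_deg)
  )
  structure(out, class = c("angle_series", class(out)),
            unwrapped = unwrapped, organ = organ)
}

series_channel <- function(series, channel = c("orientation", "roll")) {
  channel <- match.arg(channel)
  v <- if (channel == "orientation") series$orientation_deg else series$roll_deg
  if (all(is.na(v))) {
    stop("channel '", channel, "' is absent from this series")
  }
  v
}

#' In-plane orientation of a binary organ mask
#'
#' The protractor measurement formalized: the angle of the mask's principal
#' axis (from second central moments) relative to the image vertical, in
#' `(-90, 90]`, counterclockwise positive in image coordinates (y up). A
#' vertical bar scores 0, a horizontal bar 90.
#'
#' @param mask Logical or 0/1 matrix in image order (rows top-to-bottom).
#' @return Angle in degrees.
#' @export
orientation_angle <- function(mask) {
  mask <- as.matrix(mask) != 0
  if (!any(mask)) {
    stop("no foreground: mask is empty")
  }
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2]
  y <- nrow(mask) - idx[, 1]  # y up
  xc <- x - mean(x); yc <- y - mean(y)
  mu20 <- mean(xc^2); mu02 <- mean(yc^2); mu11 <- mean(xc * yc)
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)$values
  if (ev[1] <= 0 || ev[1] / max(ev[2], 1e-12) < 1.05) {
    stop("orientation undefined: mask is isotropic (principal axes degenerate)")
  }
  phi <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi  # from +x axis, CCW
  theta <- phi - 90  # from vertical, in (-180, 0]
  if (theta <= -90) theta + 180 else theta
}

#' Axial roll angle of a surface marker about the organ midline
#'
#' Azimuth of the marked reference point about the midline in the image
#' plane, measured from the +x direction, counterclockwise positive, in
#' `(-180, 180]`.
#'
#' @param midline_point,marker_point Numeric `(x, y)` image points (y up).
#' @return Angle in degrees.
#' @export
roll_angle <- function(midline_point, marker_point) {
  d <- as.numeric(marker_point) - as.numeric(midline_point)
  if (all(abs(d) < .Machine$double.eps)) {
    stop("marker on midline: roll azimuth undefined")
  }
  atan2(d[2], d[1]) * 180 / pi
}

#' Unwrap a wrapped angle series to cumulative rotation
#'
#' Successive differences are mapped into `(-180, 180]` and cumulatively
#' summed, under the assumption that true rotation between consecutive
#' observations stays below 180 degrees (weekly sampling). This makes
#' cumulative rotations beyond the wrap range — including double
#' resupination through 360 degrees — visible; wrapping the output mod 360
#' recovers the input.
#'
#' @param series An [angle_series()] with a wrapped roll channel.
#' @return The series with `roll_deg` unwrapped and `unwrapped = TRUE`.
#' @export
unwrap_series <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  if (isTRUE(attr(series, "unwrapped"))) {
    return(series)
  }
  roll <- series$roll_deg
  if (!all(is.na(roll))) {
    series$roll_deg <- unwrap_angles(roll)
  }
  attr(series, "unwrapped") <- TRUE
  series
}

unwrap_angles <- function(a) {
  if (length(a) <= 1) {
    return(a)
  }
  d <- diff(a)
  d <- d - 360 * ceiling((d - 180) / 360)  # into (-180, 180]
  cumsum(c(a[1], d))
}

#' Classify an angular change as bending, twisting and/or resupination
#'
#' Applies the movement taxonomy: a change of the long axis' orientation in
#' the vertical plane beyond tolerance is *bending*; axial (horizontal-axis)
#' rotation below 180 degrees is *twisting*; rotation of 180 up to 360
#' degrees — inverting the organ top-to-bottom — is *resupination*. Rolls
#' beyond 360 degrees count full resupination cycles plus the classification
#' of the remainder.
#'
#' @param delta_orientation Cumulative orientation change over the interval,
#'   degrees.
#' @param delta_roll Cumulative (unwrapped) roll change, degrees.
#' @param tol Minimum magnitude counted as movement (default 5 degrees,
#'   protractor precision).
#' @return Character vector (subset of `"bending"`, `"twisting"`,
#'   `"resupination"`), with attribute `cycles` giving completed 360-degree
#'   resupination cycles.
#' @export
#' @examples
#' classify_movement(0, 45)   # twisting
#' classify_movement(0, 180)  # resupination
classify_movement <- function(delta_orientation = 0, delta_roll = 0, tol = 5) {
  kinds <- character(0)
  if (abs(delta_orientation) > tol) {
    kinds <- c(kinds, "bending")
  }
  r <- abs(delta_roll)
  cycles <- 0L
  if (r > 360) {
    cycles <- as.integer(r %/% 360)
    kinds <- c(kinds, "resupination")
    rem <- r %% 360
    if (rem > tol && rem < 180) {
      kinds <- c(kinds, "twisting")
    }
  } else if (r >= 180) {
    kinds <- c(kinds, "resupination")
  } else if (r > tol) {
    kinds <- c(kinds, "twisting")
  }
  structure(unique(kinds), cycles = cycles)
}

#' Maximum angular excursion from the start of a window
#'
#' The largest absolute departure of the channel from its value at the window
#' start, over all observations inside the window, with the direction of the
#' extremal excursion (clockwise = negative change under the
#' counterclockwise-positive sign convention).
#'
#' @param series An [angle_series()].
#' @param channel `"orientation"` or `"roll"`.
#' @param window Length-2 day interval, inclusive.
#' @return Excursion magnitude in degrees, with attributes `direction`
#'   (`"clockwise"`/`"counterclockwise"`/`"none"`) and `at_day`.
#' @export
max_excursion <- function(series, channel = c("orientation", "roll"), window = NULL) {
  stopifnot(inherits(series, "angle_series"))
  v <- series_channel(series, channel)
  days <- series$day
  if (is.null(window)) {
    window <- range(days)
  }
  if (window[1] < min(days) || window[2] > max(days) || !any(days == window[1])) {
    stop("window not covered: series spans days ", min(days), "-", max(days))
  }
  inside <- days >= window[1] & days <= window[2]
  ref <- v[days == window[1]][1]
  dev <- v[inside] - ref
  i <- which.max(abs(dev))
  mag <- abs(dev[i])
  structure(
    mag,
    direction = if (mag == 0) "none" else if (dev[i] < 0) "clockwise" else "counterclockwise",
    at_day = days[inside][i]
  )
}

#' Detect movement events in an angle series
#'
#' Splits each channel (orientation; unwrapped roll) into maximal monotone
#' runs; runs whose total change reaches `min_change` become events, with the
#' kind assigned by [classify_movement()] on the run's deltas: orientation
#' runs are bending, roll runs are twisting or resupination by magnitude.
#' This is the automated counterpart of reading the start and end weeks of
#' each torsion off the time-lapse.
#'
#' @param series An [angle_series()] (wrapped roll is unwrapped first).
#' @param min_change Minimum total change in degrees (default 5).
#' @return A tibble of class `movement_events`: one row per event with
#'   `kind`, `start_day`, `end_day`, `magnitude_deg`, `direction`, `channel`,
#'   sorted by `start_day`.
#' @export
detect_events <- function(series, min_change = 5) {
  stopifnot(inherits(series, "angle_series"))
  if (nrow(series) < 2) {
    stop("at least two observations are required")
  }
  series <- unwrap_series(series)
  events <- list()
  for (channel in c("orientation", "roll")) {
    v <- if (channel == "orientation") series$orientation_deg else series$roll_deg
    if (all(is.na(v))) next
    for (run in monotone_runs(series$day, v)) {
      delta <- v[run$end] - v[run$start]
      if (abs(delta) < min_change) next
      kind <- if (channel == "orientation") {
        "bending"
      } else {
        k <- classify_movement(0, delta, tol = 0)
        if ("resupination" %in% k) "resupination" else "twisting"
      }
      events[[length(events) + 1]] <- tibble::tibble(
        kind = kind,
        start_day = series$day[run$start],
        end_day = series$day[run$end],
        magnitude_deg = abs(delta),
        direction = if (delta < 0) "clockwise" else "counterclockwise",
        channel = channel
      )
    }
  }
  out <- if (length(events)) do.call(rbind, events) else tibble::tibble(
    kind = character(0), start_day = numeric(0), end_day = numeric(0),
    magnitude_deg = numeric(0), direction = character(0), channel = character(0)
  )
  out <- out[order(out$start_day, out$channel), ]
  structure(out, class = c("movement_events", class(tibble::tibble())))
}

# maximal runs of consecutive steps sharing one nonzero sign
monotone_runs <- function(days, v) {
  steps <- sign(diff(v))
  runs <- list()
  i <- 1
  while (i <= length(steps)) {
    if (steps[i] == 0 || is.na(steps[i])) {
      i <- i + 1
      next
    }
    j <- i
    while (j < length(steps) && steps[j + 1] == steps[i]) {
      j <- j + 1
    }
    runs[[length(runs) + 1]] <- list(start = i, end = j + 1)
    i <- j + 1
  }
  runs
}

#' Day at which cumulative roll first reaches resupination
#'
#' The first observation day where the unwrapped roll has moved at least 180
#' degrees from its starting value, or `NA` if it never does.
#'
#' @param series An [angle_series()] with a roll channel.
#' @return Day (numeric) or `NA`.
#' @export
resupination_onset <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  series <- unwrap_series(series)
  roll <- series_channel(series, "roll")
  hit <- which(abs(roll - roll[1]) >= 180)
  if (length(hit) == 0) NA_real_ else series$day[hit[1]]
}

#' Write (and read back) a movement event log
#'
#' Writes one CSV row per event — the digital log that tracks significant
#' developmental changes — in deterministic `start_day` order.
#'
#' @param events A `movement_events` tibble from [detect_events()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
movement_log <- function(events, path) {
  stopifnot(inherits(events, "movement_events") || is.data.frame(events))
  events <- events[order(events$start_day, events$channel), ]
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname movement_log
#' @export
read_movement_log <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    kind = readr::col_character(),
    start_day = readr::col_double(),
    end_day = readr::col_double(),
    magnitude_deg = readr::col_double(),
    direction = readr::col_character(),
    channel = readr::col_character()
  ))
  structure(tibble::as_tibble(out), class = c("movement_events", class(tibble::tibble())))
}

#' Read an angle series from CSV
#'
#' Expects columns `day`, `orientation_deg` and/or `roll_deg`.
#'
#' @param path CSV path.
#' @param organ Organ identifier.
#' @param unwrapped Is the roll channel already cumulative?
#' @return An [angle_series()].
#' @export
read_angle_series <- function(path, organ = "organ", unwrapped = FALSE) {
  df <- readr::read_csv(path, col_types = readr::cols())
  if (!"day" %in% names(df)) {
    stop("angle CSV must have a 'day' column")
  }
  angle_series(
    days = df$day,
    orientation_deg = if ("orientation_deg" %in% names(df)) df$orientation_deg else NULL,
    roll_deg = if ("roll_deg" %in% names(df)) df$roll_deg else NULL,
    unwrapped = unwrapped, organ = organ
  )
}

#' Plot an angle series
#'
#' Orientation and roll channels against days, one panel per channel.
#'
#' @param object An [angle_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angle_series
#' @export
autoplot.angle_series <- function(object, ...) {
  long <- rbind(
    data.frame(day = object$day, angle = object$orientation_deg, channel = "orientation"),
    data.frame(day = object$day, angle = object$roll_deg, channel = "roll")
  )
  long <- long[!is.na(long$angle), ]
  ggplot2::ggplot(long, ggplot2::aes(x = day, y = angle)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "day", y = "angle (degrees)",
                  title = paste("Organ movement:", attr(object, "organ")))
}

#' Plot movement events as day-span segments
#'
#' @param object A `movement_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot movement_events
#' @export
autoplot.movement_events <- function(object, ...) {
  df <- as.data.frame(object)
  df$event <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(y = event, yend = event,
                                   x = start_day, xend = end_day,
                                   color = kind)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::labs(x = "day", y = "event", color = "kind",
                  title = "Detected movement events")
}
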