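#' Convert sampled cumulative counts into distance and velocity series
#'
#' Per sample: distance is `count * circumference`; raw velocity is the
#' per-interval increment over the sample period (sample 0 has no preceding
#' interval and is defined as 0); smoothed velocity is a trailing
#' (causal) moving average over `smooth_window` samples — the default of 4
#' matches the smoothing used when plotting average wheel speed — with
#' partial windows averaging the samples available. Samples are labelled
#' light/dark from the schedule when one is given.
#'
#' @param log A `serial_log` with monotone counts (run
#'   [detect_counter_resets()] first if needed).
#' @param sensor_id Which sensor column to convert; default the first.
#' @param schedule Optional [light_dark_schedule()] for phase labels.
#' @param smooth_window Trailing moving-average window, in samples.
#' @param circumference_cm Overrides the log header's per-sensor value.
#' @return An `activity_series` tibble: `time_s`, `count`, `distance_cm`,
#'   `velocity_raw`, `velocity_smooth` (cm/s), `phase`.
#' @export
counts_to_activity <- function(log, sensor_id = NULL, schedule = NULL,
                               smooth_window = 4, circumference_cm = NULL) {
  stopifnot(inherits(log, "serial_log"))
  if (smooth_window < 1) validation_error("smooth_window must be >= 1.")
  sensor_id <- sensor_id %||% attr(log, "sensor_ids")[1]
  if (!sensor_id %in% attr(log, "sensor_ids")) {
    validation_error(sprintf("Sensor %s is not in this log.", deparse(sensor_id)))
  }
  circ <- circumference_cm %||% attr(log, "circumference_cm")[[sensor_id]]
  period <- attr(log, "sample_period_s")
  counts <- log[[sensor_id]]
  if (length(counts) > 1 && any(diff(counts) < 0)) {
    validation_error(sprintf(
      "Cumulative counts for sensor %s are not monotone; run detect_counter_resets() first.",
      sensor_id
    ))
  }
  t_s <- log$elapsed_ms / 1000
  distance <- counts * circ
  n <- length(counts)
  if (n == 0) {
    v_raw <- v_smooth <- numeric()
  } else {
    v_raw <- c(0, diff(distance)) / period
    cs <- cumsum(v_raw)
    k <- seq_len(n)
    lower <- pmax(k - smooth_window, 0)
    v_smooth <- (cs - c(0, cs)[lower + 1]) / (k - lower)
  }
  phase <- if (is.null(schedule)) rep(NA_character_, n) else {
    phase_at(t_s, attr(log, "wall_start"), schedule)
  }
  out <- tibble::tibble(
    time_s = t_s, count = counts, distance_cm = distance,
    velocity_raw = v_raw, velocity_smooth = v_smooth, phase = phase
  )
  attr(out, "sample_period_s") <- period
  attr(out, "wall_start") <- attr(log, "wall_start")
  attr(out, "sensor_id") <- sensor_id
  attr(out, "circumference_cm") <- circ
  attr(out, "smooth_window") <- smooth_window
  class(out) <- c("activity_series", class(out))
  out
}

#' Summarise activity per contiguous light/dark interval
#'
#' One row per maximal run of constant phase (a night, a day, ...). The
#' distance attribution is exact: each sample's increment belongs to the
#' interval containing that sample, so interval distances sum to the series
#' total.
#'
#' @param series An `activity_series` (see [counts_to_activity()]).
#' @param schedule Optional [light_dark_schedule()]; recomputes phase labels
#'   when the series has none.
#' @return A tibble: `phase`, `start_s`, `end_s`, `n_samples`,
#'   `distance_cm`, `mean_velocity` (cm/s, distance over elapsed time),
#'   `peak_velocity_smooth`, `active_fraction` (share of samples with any
#'   rotation).
#' @export
summarize_phases <- function(series, schedule = NULL) {
  stopifnot(inherits(series, "activity_series"))
  if (nrow(series) == 0) {
    return(tibble::tibble(
      phase = character(), start_s = numeric(), end_s = numeric(),
      n_samples = integer(), distance_cm = numeric(), mean_velocity = numeric(),
      peak_velocity_smooth = numeric(), active_fraction = numeric()
    ))
  }
  phase <- series$phase
  if (!is.null(schedule) && all(is.na(phase))) {
    phase <- phase_at(series$time_s, attr(series, "wall_start"), schedule)
  }
  period <- attr(series, "sample_period_s")
  increments <- c(series$distance_cm[1], diff(series$distance_cm))
  r <- rle(ifelse(is.na(phase), "none", phase))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map_dfr(seq_along(r$values), function(j) {
    idx <- starts[j]:ends[j]
    dist <- sum(increments[idx])
    dur <- length(idx) * period
    tibble::tibble(
      phase = if (r$values[j] == "none") NA_character_ else r$values[j],
      start_s = series$time_s[starts[j]],
      end_s = series$time_s[ends[j]],
      n_samples = length(idx),
      distance_cm = dist,
      mean_velocity = dist / dur,
      peak_velocity_smooth = max(series$velocity_smooth[idx]),
      active_fraction = mean(series$velocity_raw[idx] > 0)
    )
  })
}

#' Detect running bouts and rest gaps
#'
#' A bout is a maximal interval over which the raw velocity stays at or
#' above `min_speed`; bouts separated by rest shorter than `min_gap_s` are
#' merged (a brief hesitation does not end a bout). Rest gaps are the
#' complementary intervals. The thresholds are conventions, not measured
#' constants, and are meant to be overridden per study.
#'
#' @param series An `activity_series`.
#' @param min_speed Minimum raw velocity (cm/s) counting as running.
#' @param min_gap_s Gaps shorter than this merge adjacent bouts.
#' @return A `bout_table` list with `$bouts` (`start_s`, `end_s`,
#'   `duration_s`, `distance_cm`, `mean_speed`) and `$rest_gaps`
#'   (`start_s`, `end_s`, `duration_s`).
#' @export
detect_bouts <- function(series, min_speed = 1, min_gap_s = 60) {
  stopifnot(inherits(series, "activity_series"))
  period <- attr(series, "sample_period_s")
  empty <- list(
    bouts = tibble::tibble(
      start_s = numeric(), end_s = numeric(), duration_s = numeric(),
      distance_cm = numeric(), mean_speed = numeric()
    ),
    rest_gaps = tibble::tibble(start_s = numeric(), end_s = numeric(), duration_s = numeric())
  )
  class(empty) <- "bout_table"
  if (nrow(series) == 0) return(empty)

  t0 <- series$time_s[1]
  t_end <- series$time_s[nrow(series)]
  active <- series$velocity_raw >= min_speed
  active[1] <- FALSE # sample 0 carries no interval
  if (!any(active)) {
    empty$rest_gaps <- tibble::tibble(start_s = t0, end_s = t_end, duration_s = t_end - t0)
    return(empty)
  }
  r <- rle(active)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- tibble::tibble(
    start_s = series$time_s[starts_i[r$values]] - period,
    end_s = series$time_s[ends_i[r$values]]
  )
  # merge runs separated by short rests
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs$start_s[i] - last$end_s < min_gap_s) {
        merged[[length(merged)]]$end_s <- runs$end_s[i]
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
  }
  bouts <- dplyr::bind_rows(merged)
  increments <- c(series$distance_cm[1], diff(series$distance_cm))
  bouts <- dplyr::mutate(bouts,
    duration_s = .data$end_s - .data$start_s,
    distance_cm = purrr::map2_dbl(.data$start_s, .data$end_s, function(a, b) {
      sum(increments[series$time_s > a + 1e-9 & series$time_s <= b + 1e-9])
    }),
    mean_speed = .data$distance_cm / .data$duration_s
  )
  gap_start <- c(t0, bouts$end_s)
  gap_end <- c(bouts$start_s, t_end)
  rest <- tibble::tibble(start_s = gap_start, end_s = gap_end, duration_s = gap_end - gap_start)
  rest <- rest[rest$duration_s > 1e-9, ]
  out <- list(bouts = bouts, rest_gaps = rest)
  class(out) <- "bout_table"
  out
}

#' @export
print.bout_table <- function(x, ...) {
  cat(sprintf("<bout_table> %d bout(s), %d rest gap(s)\n", nrow(x$bouts), nrow(x$rest_gaps)))
  print(x$bouts)
  invisible(x)
}

#' Write an activity series or phase summary as CSV
#' @param x An `activity_series` or phase-summary tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
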