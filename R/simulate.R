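#' Speed profile for a programmed constant-speed run
#'
#' A piecewise-constant rotation-rate schedule, as driven by a motorised
#' "robotic mouse" during mechanical validation of the tracker: the wheel is
#' spun at a fixed rate for each segment, with zero-rate segments as pauses.
#'
#' @param duration_s Segment durations (s), all positive.
#' @param rate_rev_s Segment rotation rates (rev/s), all non-negative;
#'   recycled against `duration_s`.
#' @return A tibble with columns `duration_s` and `rate_rev_s`, class
#'   `speed_profile`.
#' @examples
#' speed_profile(c(10, 5, 10), c(2, 0, 2))
#' @export
speed_profile <- function(duration_s, rate_rev_s) {
  if (length(duration_s) == 0) validation_error("A speed profile needs at least one segment.")
  seg <- tibble::tibble(
    duration_s = as.numeric(duration_s),
    rate_rev_s = as.numeric(rate_rev_s)
  )
  if (any(!is.finite(seg$duration_s)) || any(seg$duration_s <= 0)) {
    validation_error("Segment durations must be positive and finite.")
  }
  if (any(!is.finite(seg$rate_rev_s)) || any(seg$rate_rev_s < 0)) {
    validation_error("Rotation rates must be non-negative and finite.")
  }
  class(seg) <- c("speed_profile", class(seg))
  seg
}

#' The three-interval mechanical-validation profile
#'
#' An 85 s run/pause schedule mirroring the motorised validation of the
#' tracker: three constant-speed run intervals separated by pauses, sampled
#' downstream at 4 Hz. The default rate of 0.89 rev/s on a 50 cm wheel
#' corresponds to a linear plateau speed of 44.5 cm/s.
#'
#' @param rate_rev_s Rotation rate during the run intervals (rev/s).
#' @return A [speed_profile()] totalling 85 s.
#' @export
robotic_validation_profile <- function(rate_rev_s = 0.89) {
  speed_profile(
    duration_s = c(15, 10, 15, 10, 20, 15),
    rate_rev_s = c(rate_rev_s, 0, rate_rev_s, 0, rate_rev_s, 0)
  )
}

new_rotation_trace <- function(time_s, duration_s, wall_start) {
  out <- tibble::tibble(time_s = as.numeric(time_s))
  if (is.unsorted(out$time_s, strictly = TRUE)) {
    validation_error("Rotation times must be strictly increasing.")
  }
  if (nrow(out) > 0 && (out$time_s[1] < 0 || out$time_s[nrow(out)] > duration_s + 1e-9)) {
    validation_error("Rotation times must lie within [0, duration_s].")
  }
  attr(out, "duration_s") <- as.numeric(duration_s)
  attr(out, "wall_start") <- as_wall_start(wall_start)
  class(out) <- c("rotation_trace", class(out))
  out
}

#' Construct a ground-truth rotation trace
#'
#' The ground truth of the system: the exact times at which the wheel
#' completes a rotation (the magnet passes the sensor). An empty trace is a
#' valid "no running" record.
#'
#' @param time_s Strictly increasing rotation-completion offsets (s) from
#'   `wall_start`, all within `[0, duration_s]`.
#' @param duration_s Trace duration (s).
#' @param wall_start Absolute timestamp of offset zero (UTC).
#' @return A tibble with column `time_s`, class `rotation_trace`, carrying
#'   `duration_s` and `wall_start` attributes.
#' @export
rotation_trace <- function(time_s = numeric(),
                           duration_s,
                           wall_start = "2022-01-01T19:00:00Z") {
  new_rotation_trace(time_s, duration_s, wall_start)
}

#' Simulate a programmed constant-speed ("robotic mouse") run
#'
#' Deterministically generates the rotation times produced by spinning the
#' wheel through a piecewise-constant [speed_profile()]: within each segment
#' rotations are equally spaced at `1 / rate_rev_s`, so a segment contributes
#' `floor(duration_s * rate_rev_s)` rotations; zero-rate segments contribute
#' none.
#'
#' @param profile A [speed_profile()].
#' @param geometry A [wheel_geometry()] (carried for downstream distance
#'   conversion; does not affect rotation times).
#' @param wall_start Absolute timestamp of trace start (UTC).
#' @return A [rotation_trace()].
#' @examples
#' tr <- simulate_robotic_run(speed_profile(10, 2), wheel_geometry(15.9))
#' nrow(tr)  # 20 rotations at 0.5 s spacing
#' @export
simulate_robotic_run <- function(profile, geometry,
                                 wall_start = "2022-01-01T12:00:00Z") {
  if (!inherits(profile, "speed_profile")) {
    profile <- speed_profile(profile$duration_s, profile$rate_rev_s)
  }
  stopifnot(inherits(geometry, "wheel_geometry"))
  starts <- cumsum(c(0, head(profile$duration_s, -1)))
  times <- purrr::pmap(
    list(starts, profile$duration_s, profile$rate_rev_s),
    function(t0, dur, rate) {
      if (rate <= 0) return(numeric())
      n <- floor(dur * rate + 1e-9)
      if (n < 1) return(numeric())
      t0 + seq_len(n) / rate
    }
  )
  new_rotation_trace(
    unlist(times),
    duration_s = sum(profile$duration_s),
    wall_start = wall_start
  )
}

#' Behavioural parameters of the virtual nocturnal mouse
#'
#' Parameterises the stochastic running model: running happens in discrete
#' bouts whose onsets follow a phase-dependent Poisson process (a higher
#' bout rate in the dark phase makes the virtual animal nocturnal), bout
#' durations are gamma distributed (right-skewed, positive), and each bout
#' runs at a Gaussian-sampled linear speed clipped below at 0 cm/s. The
#' defaults are calibrated so one 12 h dark phase yields roughly 6--8 km,
#' mid-range of the 3--16 km per night reported for group-housed laboratory
#' mice.
#'
#' @param dark_bout_rate,light_bout_rate Bout onsets per hour in the dark and
#'   light phase. Non-negative; nocturnal presets keep
#'   `dark_bout_rate >= light_bout_rate`.
#' @param bout_duration_mean_s Mean bout duration (s).
#' @param bout_duration_shape Gamma shape of bout durations (dimensionless).
#' @param run_speed_mean_cm_s,run_speed_sd_cm_s Mean and SD (cm/s) of the
#'   per-bout linear running speed.
#' @param seed Integer seed making the simulation reproducible.
#' @return A `mouse_activity_params` list.
#' @export
mouse_activity_params <- function(dark_bout_rate = 20,
                                  light_bout_rate = 1,
                                  bout_duration_mean_s = 240,
                                  bout_duration_shape = 2,
                                  run_speed_mean_cm_s = 28,
                                  run_speed_sd_cm_s = 6,
                                  seed = 1L) {
  if (dark_bout_rate < 0 || light_bout_rate < 0) {
    validation_error("Bout rates must be non-negative.")
  }
  if (bout_duration_mean_s <= 0 || bout_duration_shape <= 0) {
    validation_error("Bout duration mean and shape must be positive.")
  }
  if (run_speed_mean_cm_s <= 0 || run_speed_sd_cm_s < 0) {
    validation_error("Running speed mean must be positive and its SD non-negative.")
  }
  structure(
    list(
      dark_bout_rate = dark_bout_rate,
      light_bout_rate = light_bout_rate,
      bout_duration_mean_s = bout_duration_mean_s,
      bout_duration_shape = bout_duration_shape,
      run_speed_mean_cm_s = run_speed_mean_cm_s,
      run_speed_sd_cm_s = run_speed_sd_cm_s,
      seed = as.integer(seed)
    ),
    class = "mouse_activity_params"
  )
}

#' Simulate voluntary running by a virtual nocturnal mouse
#'
#' Generates a ground-truth [rotation_trace()] from the bout model described
#' in [mouse_activity_params()]: rest and run alternate; bout onsets are a
#' phase-modulated Poisson process (simulated by thinning), bout durations
#' are gamma, and within a bout rotations are equally spaced at
#' `circumference / speed` seconds. The whole trace is reproducible from the
#' seed.
#'
#' @param params A [mouse_activity_params()].
#' @param schedule A [light_dark_schedule()].
#' @param duration_s Simulated duration (s), positive.
#' @param geometry A [wheel_geometry()]; the sampled linear speed divided by
#'   the circumference gives the within-bout rotation rate.
#' @param wall_start Absolute timestamp of trace start; defaults to an
#'   evening dark-onset start, matching overnight tracking sessions.
#' @param seed Overrides `params$seed` when given.
#' @return A [rotation_trace()].
#' @export
simulate_mouse_activity <- function(params,
                                    schedule,
                                    duration_s,
                                    geometry,
                                    wall_start = "2022-01-01T19:00:00Z",
                                    seed = NULL) {
  stopifnot(inherits(params, "mouse_activity_params"),
            inherits(schedule, "light_dark_schedule"),
            inherits(geometry, "wheel_geometry"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    validation_error("duration_s must be positive.")
  }
  seed <- seed %||% params$seed
  wall_start <- as_wall_start(wall_start)
  lam_dark <- params$dark_bout_rate / 3600
  lam_light <- params$light_bout_rate / 3600
  lam_max <- max(lam_dark, lam_light)

  times <- withr::with_seed(seed, {
    acc <- list()
    t <- 0
    while (lam_max > 0 && t < duration_s) {
      # next bout onset by thinning against the phase-dependent rate
      repeat {
        t <- t + rexp(1, lam_max)
        if (t >= duration_s) break
        lam <- if (phase_at(t, wall_start, schedule) == "dark") lam_dark else lam_light
        if (runif(1) <= lam / lam_max) break
      }
      if (t >= duration_s) break
      bout_dur <- rgamma(1, shape = params$bout_duration_shape,
                         rate = params$bout_duration_shape / params$bout_duration_mean_s)
      speed <- max(rnorm(1, params$run_speed_mean_cm_s, params$run_speed_sd_cm_s), 0)
      rate <- speed / geometry$circumference_cm
      run_dur <- min(bout_dur, duration_s - t)
      if (rate > 0) {
        n <- floor(run_dur * rate)
        if (n >= 1) acc[[length(acc) + 1]] <- t + seq_len(n) / rate
      }
      t <- t + bout_dur
    }
    unlist(acc) %||% numeric()
  })
  new_rotation_trace(times, duration_s = duration_s, wall_start = wall_start)
}

#' Ground-truth distance of a rotation trace
#'
#' @param trace A [rotation_trace()].
#' @param geometry A [wheel_geometry()].
#' @return Total distance in cm: `nrow(trace) * circumference_cm`, exactly.
#' @export
trace_total_distance <- function(trace, geometry) {
  stopifnot(inherits(trace, "rotation_trace"), inherits(geometry, "wheel_geometry"))
  nrow(trace) * geometry$circumference_cm
}

#' Write a ground-truth trace as a two-column CSV
#'
#' @param trace A [rotation_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "rotation_trace"))
  out <- tibble::tibble(rotation_index = seq_len(nrow(trace)), time_s = trace$time_s)
  readr::write_csv(out, path)
  invisible(path)
}
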