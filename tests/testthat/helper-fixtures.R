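# Shared fixtures: a 50 cm wheel (round numbers), the facility 12/12
# schedule, and the 85 s three-interval mechanical-validation run.

fixture_geometry <- function() wheel_geometry(circumference_cm = 50)

fixture_schedule <- function() light_dark_schedule("19:00", "07:00")

# run/pause boundaries of robotic_validation_profile(): runs at 0-15, 25-40,
# 50-70 s; pauses at 15-25, 40-50, 70-85 s
fixture_pauses <- function() {
  rbind(c(15, 25), c(40, 50), c(70, 85))
}

ideal_sensor <- function() sensor_config(refractory_ms = 0)

# independent oracle: event-by-event accumulation of wheel angle at 1 ms
# resolution, counting each completed revolution, segment phase reset
oracle_rotation_count <- function(profile, dt = 1e-3) {
  total <- 0L
  for (i in seq_len(nrow(profile))) {
    steps <- round(profile$duration_s[i] / dt)
    if (steps == 0 || profile$rate_rev_s[i] == 0) next
    ang <- cumsum(rep(profile$rate_rev_s[i] * dt, steps))
    total <- total + sum(diff(floor(c(0, ang + 1e-9))) > 0)
  }
  total
}

# a random rotation trace with distinct times on a 1 ms grid
random_trace <- function(n, duration_s, wall_start = "2022-01-01T19:00:00Z") {
  grid <- seq(0.001, duration_s - 0.001, by = 0.001)
  rotation_trace(sort(sample(grid, min(n, length(grid)))), duration_s, wall_start)
}

# an overnight two-sensor log: sensor sA turns all night, sensor sB freezes
# at freeze_s; steady one rotation per 5 s, sampled every 10 s
fixture_jam_log <- function(duration_s = 43200, freeze_s = 14400,
                            sensors = c("sA", "sB")) {
  mk <- function(sid, until) {
    times <- seq(5, until, by = 5)
    tibble::tibble(sensor_id = sid, time_s = times)
  }
  # the last sensor freezes at freeze_s; any others keep running
  ev <- dplyr::bind_rows(c(
    lapply(head(sensors, -1), mk, until = duration_s),
    list(mk(tail(sensors, 1), freeze_s))
  ))
  sample_counts(ev, sample_rate_hz = 0.1, duration_s = duration_s,
                wall_start = "2022-01-01T19:00:00Z", circumference_cm = 50,
                sensor_ids = sensors)
}

fixture_config <- function(sensors = c("sA", "sB")) {
  experiment_config(
    tibble::tibble(
      cage = paste0("cage", seq_along(sensors)),
      sensor_id = sensors, circumference_cm = 50, group_size = 1L
    ),
    schedule = fixture_schedule()
  )
}
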