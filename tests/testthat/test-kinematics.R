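constant_run_series <- function(rate_rev_s = 2, duration_s = 30,
                                sample_rate_hz = 4, smooth_window = 4) {
  geom <- fixture_geometry()
  tr <- simulate_robotic_run(speed_profile(duration_s, rate_rev_s), geom)
  ev <- sense_rotations(tr, ideal_sensor())
  log <- sample_counts(ev, sample_rate_hz, duration_s, circumference_cm = 50)
  counts_to_activity(log, smooth_window = smooth_window)
}

test_that("constant-rate running settles at rate times circumference", {
  ser <- constant_run_series(rate_rev_s = 2) # 2 rev/s * 50 cm = 100 cm/s
  # raw velocity alternates around the true speed; the 4-sample average
  # settles exactly once the window is full
  expect_equal(unique(ser$velocity_smooth[ser$time_s >= 1]), 100)
  expect_true(all(ser$velocity_raw >= 0))
  expect_true(all(diff(ser$distance_cm) >= 0))
})

test_that("smoothed velocity is exactly zero through pause tails", {
  geom <- fixture_geometry()
  tr <- simulate_robotic_run(robotic_validation_profile(), geom)
  log <- sample_counts(sense_rotations(tr, sensor_config()), 4, 85,
                       circumference_cm = 50)
  ser <- counts_to_activity(log, smooth_window = 4)
  for (i in seq_len(nrow(fixture_pauses()))) {
    p <- fixture_pauses()[i, ]
    sel <- ser$time_s >= p[1] + 1 & ser$time_s <= p[2] # window (4 samples) cleared
    expect_true(any(sel))
    expect_identical(max(ser$velocity_smooth[sel]), 0)
  }
})

test_that("an empty (header-only) log yields an empty series", {
  txt <- paste(
    "# version=1", "# wall_start=2022-01-01T19:00:00Z",
    "# sample_period_s=0.25", "# sensors=s1", "# dialect=counts",
    "# circumference_cm.s1=50", "", sep = "\n"
  )
  ser <- counts_to_activity(parse_log(txt))
  expect_equal(nrow(ser), 0)
  expect_equal(nrow(summarize_phases(ser)), 0)
  expect_equal(nrow(detect_bouts(ser)$bouts), 0)
})

test_that("non-monotone logs are redirected to detect_counter_resets", {
  txt <- paste(
    "# version=1", "# wall_start=2022-01-01T19:00:00Z",
    "# sample_period_s=0.25", "# sensors=s1", "# dialect=counts",
    "# circumference_cm.s1=50",
    "0\t0", "250\t5", "500\t2", "", sep = "\n"
  )
  log <- suppressWarnings(parse_log(txt, strict = FALSE))
  expect_error(counts_to_activity(log), regexp = "detect_counter_resets",
               class = "wheeltracker_validation_error")
  expect_silent(counts_to_activity(detect_counter_resets(log)))
})

test_that("raw velocity telescopes back to the final distance", {
  set.seed(31)
  for (i in 1:20) {
    tr <- random_trace(sample(1:400, 1), runif(1, 10, 200))
    rate <- sample(c(1, 2, 4), 1)
    dur <- ceiling(attr(tr, "duration_s") * rate) / rate
    log <- sample_counts(sense_rotations(tr, ideal_sensor()), rate, dur,
                         circumference_cm = 50)
    ser <- counts_to_activity(log)
    expect_equal(sum(ser$velocity_raw) / rate, ser$distance_cm[nrow(ser)])
  }
})

test_that("smoothing preserves the mean over constant-rate runs", {
  ser <- constant_run_series(rate_rev_s = 2, duration_s = 40)
  lead_in <- ser$time_s > 1 # whole rotations per window beyond this point
  expect_equal(mean(ser$velocity_smooth[lead_in]), mean(ser$velocity_raw[lead_in]),
               tolerance = 1e-6)
})

test_that("pipeline distance equals ground truth under an ideal sensor", {
  geom <- fixture_geometry()
  tr <- simulate_robotic_run(robotic_validation_profile(), geom)
  log <- sample_counts(sense_rotations(tr, ideal_sensor()), 4, 85,
                       circumference_cm = 50)
  ser <- counts_to_activity(log)
  expect_identical(ser$distance_cm[nrow(ser)], trace_total_distance(tr, geom))
})

test_that("phase summaries split a 50 h recording and conserve distance", {
  geom <- fixture_geometry()
  sched <- fixture_schedule()
  params <- mouse_activity_params(seed = 21)
  dur <- 50 * 3600
  tr <- simulate_mouse_activity(params, sched, dur, geom,
                                wall_start = "2022-01-01T19:00:00Z")
  log <- sample_counts(sense_rotations(tr, sensor_config()), 1 / 30, dur,
                       wall_start = "2022-01-01T19:00:00Z", circumference_cm = 50)
  ser <- counts_to_activity(log, schedule = sched)
  phases <- summarize_phases(ser)
  expect_gte(nrow(phases), 4) # 2 nights, 2 days, plus the trailing phase
  expect_equal(sum(phases$distance_cm), ser$distance_cm[nrow(ser)])
  expect_true(all(phases$phase %in% c("light", "dark")))
  # dark rows dominate the running
  dark_dist <- sum(phases$distance_cm[phases$phase == "dark"])
  expect_gt(dark_dist / sum(phases$distance_cm), 0.8)
})

test_that("a run with no schedule crossing summarises to a single row", {
  ser <- constant_run_series(rate_rev_s = 1, duration_s = 20)
  phases <- summarize_phases(ser)
  expect_equal(nrow(phases), 1)
  expect_equal(phases$distance_cm, ser$distance_cm[nrow(ser)])
  expect_true(is.na(phases$phase))
})

test_that("all dark activity leaves zero-distance light rows", {
  sched <- fixture_schedule()
  # run only the first 2 h of dark, record over 14 h into the light phase
  ev <- tibble::tibble(sensor_id = "s1", time_s = seq(5, 7200, by = 5))
  log <- sample_counts(ev, 0.1, 14 * 3600, wall_start = "2022-01-01T19:00:00Z",
                       circumference_cm = 50)
  phases <- summarize_phases(counts_to_activity(log, schedule = sched))
  expect_equal(sum(phases$distance_cm[phases$phase == "light"]), 0)
  expect_gt(sum(phases$distance_cm[phases$phase == "dark"]), 0)
})

test_that("bout detection recovers the three programmed run intervals", {
  geom <- fixture_geometry()
  tr <- simulate_robotic_run(robotic_validation_profile(), geom)
  log <- sample_counts(sense_rotations(tr, sensor_config()), 4, 85,
                       circumference_cm = 50)
  ser <- counts_to_activity(log)
  bt <- detect_bouts(ser, min_speed = 1, min_gap_s = 5) # pauses are 10-15 s
  expect_equal(nrow(bt$bouts), 3)
  expect_equal(sum(bt$bouts$distance_cm), ser$distance_cm[nrow(ser)])

  # a gap threshold above every pause merges everything into one bout
  merged <- detect_bouts(ser, min_speed = 1, min_gap_s = 30)
  expect_equal(nrow(merged$bouts), 1)

  # a speed floor above the peak finds no bouts, one all-covering rest gap
  none <- detect_bouts(ser, min_speed = 1000, min_gap_s = 5)
  expect_equal(nrow(none$bouts), 0)
  expect_equal(nrow(none$rest_gaps), 1)
  expect_equal(none$rest_gaps$duration_s, 85)
})

test_that("activity and permutation plots build without error", {
  ser <- constant_run_series()
  p1 <- autoplot(ser)
  expect_s3_class(p1, "ggplot")
  d <- paired_design(paste0("c", 1:6), rep(100, 6), c(120, 130, 90, 140, 150, 110))
  p2 <- autoplot(permutation_test(d, 200, seed = 1))
  expect_s3_class(p2, "ggplot")
})
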