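#' Hall-sensor behaviour model
#'
#' Knobs for the emulated magnetic sensor. The physical device is treated as
#' essentially exact — one trigger per rotation — so the default is an ideal
#' sensor with a short 50 ms refractory period (suppressing double counts if
#' the magnet dithers over the sensor) and no jitter or missed triggers. The
#' imperfection knobs exist for robustness testing of the analysis chain.
#'
#' @param refractory_ms Minimum time (ms) after an accepted trigger during
#'   which further triggers are ignored. Non-negative.
#' @param trigger_jitter_ms SD (ms) of Gaussian timing jitter on each trigger.
#' @param miss_probability Probability of a rotation failing to trigger;
#'   must lie in `[0, 1)`.
#' @return A `sensor_config` list.
#' @export
sensor_config <- function(refractory_ms = 50,
                          trigger_jitter_ms = 0,
                          miss_probability = 0) {
  if (refractory_ms < 0) validation_error("refractory_ms must be non-negative.")
  if (trigger_jitter_ms < 0) validation_error("trigger_jitter_ms must be non-negative.")
  if (miss_probability < 0 || miss_probability >= 1) {
    validation_error("miss_probability must lie in [0, 1).")
  }
  structure(
    list(
      refractory_ms = refractory_ms,
      trigger_jitter_ms = trigger_jitter_ms,
      miss_probability = miss_probability
    ),
    class = "sensor_config"
  )
}

#' Convert wheel rotations into sensor trigger events
#'
#' Emulates one Hall-effect sensor watching the magnet: each rotation
#' produces one trigger (optionally jittered in time and randomly missed),
#' and triggers arriving within the refractory period of the previously
#' accepted trigger are suppressed. With an ideal configuration (no jitter,
#' no misses, zero refractory — or any refractory shorter than the minimum
#' rotation spacing) the trigger times equal the rotation times exactly.
#'
#' @param trace A [rotation_trace()].
#' @param config A [sensor_config()].
#' @param seed Integer seed for jitter/miss randomness; only consulted when
#'   the config is stochastic.
#' @param sensor_id Label for the emulated sensor.
#' @return A tibble with columns `sensor_id`, `time_s` (increasing trigger
#'   offsets), class `sensor_events`, with the trace duration and wall start
#'   carried as attributes.
#' @export
sense_rotations <- function(trace, config = sensor_config(), seed = 1L,
                            sensor_id = "s1") {
  stopifnot(inherits(trace, "rotation_trace"), inherits(config, "sensor_config"))
  duration_s <- attr(trace, "duration_s")
  times <- trace$time_s

  stochastic <- config$trigger_jitter_ms > 0 || config$miss_probability > 0
  if (stochastic) {
    times <- withr::with_seed(seed, {
      t <- times
      if (config$trigger_jitter_ms > 0) {
        t <- t + rnorm(length(t), sd = config$trigger_jitter_ms / 1000)
        t <- pmin(pmax(t, 0), duration_s)
        t <- sort(t)
      }
      if (config$miss_probability > 0) {
        t <- t[runif(length(t)) >= config$miss_probability]
      }
      t
    })
  }

  refr_s <- config$refractory_ms / 1000
  if (refr_s > 0 && length(times) > 1) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= refr_s - 1e-12) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }

  out <- tibble::tibble(sensor_id = rep(sensor_id, length(times)), time_s = times)
  attr(out, "duration_s") <- duration_s
  attr(out, "wall_start") <- attr(trace, "wall_start")
  class(out) <- c("sensor_events", class(out))
  out
}

new_serial_log <- function(samples, sample_period_s, wall_start, sensor_ids,
                           circumference_cm, dialect = "counts",
                           metadata = list()) {
  wall_start <- as_wall_start(wall_start)
  circumference_cm <- setNames(as.numeric(circumference_cm), sensor_ids)
  out <- tibble::as_tibble(samples)
  attr(out, "sample_period_s") <- as.numeric(sample_period_s)
  attr(out, "wall_start") <- wall_start
  attr(out, "sensor_ids") <- sensor_ids
  attr(out, "circumference_cm") <- circumference_cm
  attr(out, "dialect") <- dialect
  attr(out, "metadata") <- if (length(metadata)) metadata else list()
  class(out) <- c("serial_log", class(out))
  out
}

#' Sample trigger streams into a cumulative-count serial log
#'
#' Emulates the microcontroller's fixed-rate serial reporting: at every
#' sample instant `k * sample_period` (including `t = 0`) it writes, per
#' sensor, the cumulative number of triggers observed so far. A trigger
#' falling exactly on a sample instant is included in that sample. No
#' trigger is ever lost by sampling — only delayed into the next line, which
#' is exactly the transient between-sensor "misalignment" visible when the
#' rotation period beats against the refresh rate; the final sample always
#' holds each stream's total trigger count.
#'
#' @param events A tibble of trigger events with columns `sensor_id`,
#'   `time_s` (e.g. [sense_rotations()] output, or several of them bound by
#'   row). All triggers must fall within `[0, duration_s]`.
#' @param sample_rate_hz Sampling frequency (Hz), positive. The validation
#'   runs use 4 Hz (a 0.25 s refresh).
#' @param duration_s Recording duration (s). The log holds
#'   `floor(duration_s * sample_rate_hz) + 1` samples.
#' @param wall_start Absolute timestamp of sample zero (UTC); defaults to
#'   the events' trace start.
#' @param circumference_cm Wheel circumference per sensor (scalar recycled,
#'   or named vector by sensor id); recorded in the log header.
#' @param sensor_ids Sensor ordering for the log columns; defaults to order
#'   of appearance in `events`. Sensors with no events may be named here.
#' @param dialect `"counts"` (canonical, lossless integer counts) or
#'   `"distance_cm"` (counts rendered as cm on the wire).
#' @return A `serial_log`: a tibble with column `elapsed_ms` plus one
#'   cumulative-count column per sensor, carrying the sampling metadata as
#'   attributes.
#' @export
sample_counts <- function(events, sample_rate_hz, duration_s,
                          wall_start = NULL, circumference_cm = 50,
                          sensor_ids = NULL, dialect = "counts") {
  if (!is.data.frame(events) || !all(c("sensor_id", "time_s") %in% names(events))) {
    validation_error("events must be a data frame with sensor_id and time_s columns.")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    validation_error("sample_rate_hz must be positive.")
  }
  if (nrow(events) > 0 && any(events$time_s < 0)) {
    validation_error("events contains negative trigger times.")
  }
  sensor_ids <- sensor_ids %||% unique(events$sensor_id)
  if (length(sensor_ids) == 0) validation_error("No sensors named and no events given.")
  wall_start <- wall_start %||% attr(events, "wall_start") %||% "2022-01-01T19:00:00Z"
  if (length(circumference_cm) == 1) {
    circumference_cm <- rep(circumference_cm, length(sensor_ids))
  } else if (!is.null(names(circumference_cm))) {
    circumference_cm <- circumference_cm[sensor_ids]
  }
  if (length(circumference_cm) != length(sensor_ids) || anyNA(circumference_cm)) {
    validation_error("circumference_cm must supply one value per sensor.")
  }

  period <- 1 / sample_rate_hz
  n_samples <- floor(duration_s / period + 1e-9) + 1
  t_k <- (seq_len(n_samples) - 1) * period
  # the recording window is quantized to whole periods: a trigger after the
  # final sample instant would silently vanish, so reject it instead
  if (nrow(events) > 0 && any(events$time_s > t_k[n_samples] + 1e-9)) {
    validation_error(paste0(
      "events contains triggers after the final sample instant (",
      format_number(t_k[n_samples]),
      " s); extend duration_s to a whole number of sample periods covering the trace."
    ))
  }

  cols <- lapply(sensor_ids, function(sid) {
    tt <- sort(events$time_s[events$sensor_id == sid])
    as.integer(findInterval(t_k + 1e-9, tt))
  })
  names(cols) <- sensor_ids
  samples <- tibble::tibble(elapsed_ms = as.integer(round(t_k * 1000)), !!!cols)

  new_serial_log(samples, sample_period_s = period, wall_start = wall_start,
                 sensor_ids = sensor_ids, circumference_cm = circumference_cm,
                 dialect = dialect)
}

#' @export
print.serial_log <- function(x, ...) {
  cat(sprintf(
    "<serial_log> %d samples x %d sensor(s) @ %.4g s period, dialect=%s, start %s\n",
    nrow(x), length(attr(x, "sensor_ids")), attr(x, "sample_period_s"),
    attr(x, "dialect"), format_wall_start(attr(x, "wall_start"))
  ))
  NextMethod()
}

format_number <- function(x) {
  # shortest decimal representation, no scientific notation
  s <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
  ifelse(grepl(".", s, fixed = TRUE), sub("\\.?0+$", "", s), s)
}

#' Serialise a serial log to its on-disk text dialect
#'
#' The canonical dialect is header lines beginning `#` holding `key=value`
#' metadata (version, ISO-8601 wall start, sample period, sensor list,
#' dialect, per-sensor circumference), followed by one tab-separated line
#' per sample: elapsed milliseconds then one field per sensor. The `counts`
#' dialect stores lossless integer cumulative counts; `distance_cm` stores
#' the derived distance (count times circumference) to 0.1 cm. UTF-8, LF
#' line endings. [parse_log()] is its exact inverse.
#'
#' @param log A `serial_log` (see [sample_counts()]).
#' @param path Optional output path; when given the text is written there.
#' @param dialect Overrides the log's dialect on the wire.
#' @return The log text as a single string (invisibly when `path` is given).
#' @export
write_log <- function(log, path = NULL, dialect = NULL) {
  stopifnot(inherits(log, "serial_log"))
  dialect <- dialect %||% attr(log, "dialect")
  if (!dialect %in% c("counts", "distance_cm")) {
    validation_error(sprintf("Unknown log dialect %s.", deparse(dialect)))
  }
  sensor_ids <- attr(log, "sensor_ids")
  circ <- attr(log, "circumference_cm")
  header <- c(
    "# version=1",
    paste0("# wall_start=", format_wall_start(attr(log, "wall_start"))),
    paste0("# sample_period_s=", format_number(attr(log, "sample_period_s"))),
    paste0("# sensors=", paste(sensor_ids, collapse = ",")),
    paste0("# dialect=", dialect),
    vapply(sensor_ids, function(sid) {
      paste0("# circumference_cm.", sid, "=", format_number(circ[[sid]]))
    }, character(1))
  )
  extra <- attr(log, "metadata")
  if (length(extra)) {
    header <- c(header, vapply(names(extra), function(k) {
      paste0("# ", k, "=", as.character(extra[[k]])
      )
    }, character(1)))
  }
  data_lines <- character(0)
  if (nrow(log) > 0) {
    fields <- lapply(sensor_ids, function(sid) {
      if (dialect == "counts") {
        format_number(log[[sid]])
      } else {
        sprintf("%.1f", log[[sid]] * circ[[sid]])
      }
    })
    data_lines <- do.call(paste, c(list(format_number(log$elapsed_ms)), fields, sep = "\t"))
  }
  text <- paste0(paste(c(header, data_lines), collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL, useBytes = TRUE)
    return(invisible(text))
  }
  text
}
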