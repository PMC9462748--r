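REQUIRED_HEADER_KEYS <- c("version", "wall_start", "sample_period_s", "sensors", "dialect")

#' Parse a serial activity log
#'
#' Exact inverse of [write_log()]: reads the `#`-prefixed `key=value` header
#' and the tab-separated sample lines into a `serial_log` tibble. Malformed
#' lines are reported with their line numbers. In the `distance_cm` dialect
#' the wire values are converted back to integer counts using the per-sensor
#' circumference from the header.
#'
#' A cumulative count that decreases indicates an acquisition restart
#' (sensors re-aligned after cage cleaning, counters re-zeroed). With
#' `strict = TRUE` (default) this is a parse error naming the sample index;
#' with `strict = FALSE` the log is returned as-is with a warning so it can
#' be repaired by [detect_counter_resets()].
#'
#' @param x Log text (a single string or character vector of lines) or a
#'   path to a log file.
#' @param strict Error on non-monotone cumulative counts?
#' @return A `serial_log` (see [sample_counts()]).
#' @export
parse_log <- function(x, strict = TRUE) {
  lines <- if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, encoding = "UTF-8")
  } else if (length(x) == 1) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
  is_header <- grepl("^#", lines)
  n_header <- match(FALSE, is_header, nomatch = length(lines) + 1) - 1
  header_lines <- lines[seq_len(n_header)]
  data_lines <- lines[seq_len(length(lines) - n_header) + n_header]
  data_lines <- data_lines[nzchar(data_lines)]

  kv <- list()
  for (i in seq_along(header_lines)) {
    body <- sub("^#\\s*", "", header_lines[i])
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 1) {
      validation_error(sprintf("Malformed header at line %d: %s", i, deparse(header_lines[i])))
    }
    kv[[substr(body, 1, eq - 1)]] <- substr(body, eq + 1, nchar(body))
  }
  missing <- setdiff(REQUIRED_HEADER_KEYS, names(kv))
  if (length(missing)) {
    validation_error(paste0("Missing required header key(s): ", paste(missing, collapse = ", ")))
  }
  sensor_ids <- strsplit(kv$sensors, ",", fixed = TRUE)[[1]]
  dialect <- kv$dialect
  if (!dialect %in% c("counts", "distance_cm")) {
    validation_error(sprintf("Unknown dialect %s in header.", deparse(dialect)))
  }
  circ_keys <- paste0("circumference_cm.", sensor_ids)
  if (!all(circ_keys %in% names(kv))) {
    validation_error(paste0(
      "Missing required header key(s): ",
      paste(setdiff(circ_keys, names(kv)), collapse = ", ")
    ))
  }
  circ <- setNames(as.numeric(unlist(kv[circ_keys])), sensor_ids)
  known <- c(REQUIRED_HEADER_KEYS, circ_keys)
  metadata <- kv[setdiff(names(kv), known)]

  n_fields <- 1 + length(sensor_ids)
  parsed <- matrix(0, nrow = length(data_lines), ncol = n_fields)
  for (i in seq_along(data_lines)) {
    parts <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != n_fields || anyNA(vals)) {
      validation_error(sprintf(
        "Malformed data line %d (expected %d tab-separated numeric fields): %s",
        n_header + i, n_fields, deparse(data_lines[i])
      ))
    }
    parsed[i, ] <- vals
  }
  counts <- parsed[, -1, drop = FALSE]
  if (dialect == "distance_cm" && nrow(counts) > 0) {
    counts <- round(sweep(counts, 2, circ, "/"))
  }
  storage.mode(counts) <- "integer"

  for (j in seq_along(sensor_ids)) {
    col <- counts[, j]
    if (length(col) > 1) {
      bad <- which(diff(col) < 0)
      if (length(bad)) {
        msg <- sprintf(
          "Cumulative count for sensor %s decreases at sample %d (log line %d); if this is an acquisition restart, parse with strict = FALSE and run detect_counter_resets().",
          sensor_ids[j], bad[1] + 1, n_header + bad[1] + 1
        )
        if (strict) validation_error(msg) else warn(msg)
      }
    }
  }

  samples <- tibble::tibble(
    elapsed_ms = as.integer(parsed[, 1]),
    !!!setNames(lapply(seq_along(sensor_ids), function(j) counts[, j]), sensor_ids)
  )
  new_serial_log(samples,
    sample_period_s = as.numeric(kv$sample_period_s),
    wall_start = kv$wall_start, sensor_ids = sensor_ids,
    circumference_cm = circ, dialect = dialect, metadata = metadata
  )
}

#' Splice acquisition restarts back into monotone cumulative counts
#'
#' A sensor realignment or power cycle re-zeroes the microcontroller's
#' counters, so a cumulative column can drop mid-log. Any decrease is
#' interpreted as a restart: the value after the drop counts rotations since
#' the restart, so subsequent samples are re-based by the pre-drop total.
#' Output columns are always monotone and every observed increment is
#' preserved across the splice.
#'
#' @param log A `serial_log` (possibly non-monotone; parse with
#'   `strict = FALSE`).
#' @return The re-based `serial_log`; a `resets` attribute lists the splice
#'   points as a tibble (`sensor_id`, `sample`).
#' @examples
#' # a column 0,5,9,2,6 re-bases to 0,5,9,11,15
#' @export
detect_counter_resets <- function(log) {
  stopifnot(inherits(log, "serial_log"))
  resets <- list()
  for (sid in attr(log, "sensor_ids")) {
    x <- log[[sid]]
    if (length(x) < 2) next
    d <- diff(x)
    drops <- which(d < 0)
    if (length(drops) == 0) next
    offset <- cumsum(c(0, ifelse(d < 0, x[-length(x)], 0)))
    log[[sid]] <- as.integer(x + offset)
    resets[[sid]] <- tibble::tibble(sensor_id = sid, sample = drops + 1L)
  }
  attr(log, "resets") <- if (length(resets)) dplyr::bind_rows(resets) else
    tibble::tibble(sensor_id = character(), sample = integer())
  log
}

#' Experiment configuration
#'
#' Binds cage labels to sensors and wheel geometry, states the facility
#' light/dark schedule, and optionally the paired before/after recording
#' design. One configuration describes one experiment.
#'
#' @param cages A data frame with columns `cage`, `sensor_id`,
#'   `circumference_cm` and optionally `group_size` (mice per cage,
#'   default 1).
#' @param schedule A [light_dark_schedule()].
#' @param design Optional named list describing the paired design, e.g.
#'   `list(before = "night1.log", after = "night2.log")`.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(cages, schedule = light_dark_schedule(), design = NULL) {
  cages <- tibble::as_tibble(cages)
  need <- c("cage", "sensor_id", "circumference_cm")
  if (!all(need %in% names(cages))) {
    validation_error(paste0("cages needs columns: ", paste(need, collapse = ", ")))
  }
  if (!"group_size" %in% names(cages)) cages$group_size <- 1L
  if (anyDuplicated(cages$sensor_id)) validation_error("sensor_ids must be unique.")
  if (anyDuplicated(cages$cage)) validation_error("cage labels must be unique.")
  if (any(cages$group_size < 1)) validation_error("group_size must be >= 1.")
  if (any(cages$circumference_cm <= 0)) validation_error("circumference_cm must be positive.")
  structure(
    list(cages = cages, schedule = schedule, design = design),
    class = "experiment_config"
  )
}

#' Read / write an experiment configuration (YAML)
#'
#' @param path File path.
#' @return `read_experiment_config()` returns an [experiment_config()];
#'   `write_experiment_config()` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    validation_error(sprintf("Config file %s does not exist.", deparse(path)))
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$cages)) validation_error("Config is missing the cages section.")
  cages <- dplyr::bind_rows(lapply(y$cages, tibble::as_tibble))
  cages$circumference_cm <- as.numeric(cages$circumference_cm)
  if ("group_size" %in% names(cages)) cages$group_size <- as.integer(cages$group_size)
  sched <- light_dark_schedule(
    y$schedule$dark_onset %||% "19:00",
    y$schedule$dark_offset %||% "07:00"
  )
  experiment_config(cages, sched, design = y$design)
}

#' @rdname read_experiment_config
#' @param config An [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  fmt <- function(s) sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
  y <- list(
    cages = lapply(seq_len(nrow(config$cages)), function(i) {
      r <- config$cages[i, ]
      list(cage = r$cage, sensor_id = r$sensor_id,
           circumference_cm = r$circumference_cm,
           group_size = as.integer(r$group_size))
    }),
    schedule = list(
      dark_onset = fmt(config$schedule$dark_onset_s),
      dark_offset = fmt(config$schedule$dark_offset_s)
    ),
    design = config$design
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Quality-control scan of a serial log
#'
#' Flags acquisition problems without ever mutating the data:
#' \describe{
#'   \item{flatline}{a sensor shows zero count increase for at least
#'     `flatline_window_s` (restricted to the dark phase when
#'     `dark_only = TRUE`, when a healthy wheel should be turning) — the
#'     signature of a wheel jammed by bedding. Severity is `"exclude"` when
#'     at least one other sensor is active over the same interval (so the
#'     facility was clearly not globally quiet), otherwise `"warning"`.}
#'   \item{counter_reset}{a cumulative column decreases; see
#'     [detect_counter_resets()].}
#'   \item{missing_sensor}{a sensor named in the configuration is absent
#'     from the log.}
#' }
#' Exclusion is advisory: the findings list cages recommended for removal,
#' and downstream statistics take an explicit exclusion list — data is never
#' silently dropped.
#'
#' @param log A `serial_log`.
#' @param config An [experiment_config()] mapping sensors to cages.
#' @param flatline_window_s Minimum flat interval (s) to flag; default 2 h.
#' @param dark_only Only count flat time that falls in the dark phase?
#' @return A `qc_report`: a tibble of findings (`cage`, `sensor_id`, `kind`,
#'   `start_s`, `end_s`, `severity`) with an `excluded_cages` attribute.
#' @export
qc_scan <- function(log, config, flatline_window_s = 7200, dark_only = TRUE) {
  stopifnot(inherits(log, "serial_log"), inherits(config, "experiment_config"))
  period <- attr(log, "sample_period_s")
  wall_start <- attr(log, "wall_start")
  sensor_ids <- attr(log, "sensor_ids")
  t_s <- log$elapsed_ms / 1000
  findings <- list()
  add <- function(cage, sid, kind, start_s, end_s, severity) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      cage = cage, sensor_id = sid, kind = kind,
      start_s = start_s, end_s = end_s, severity = severity
    )
  }
  cage_of <- setNames(config$cages$cage, config$cages$sensor_id)

  for (sid in setdiff(config$cages$sensor_id, sensor_ids)) {
    add(cage_of[[sid]], sid, "missing_sensor", 0, max(t_s, 0), "exclude")
  }

  scan_ids <- intersect(config$cages$sensor_id, sensor_ids)
  if (nrow(log) >= 2 && length(scan_ids)) {
    phase <- if (dark_only) phase_at(t_s[-1], wall_start, config$schedule) else NULL
    inc <- lapply(scan_ids, function(sid) diff(log[[sid]]))
    names(inc) <- scan_ids
    for (sid in scan_ids) {
      d <- inc[[sid]]
      if (any(d < 0)) {
        k <- which(d < 0)[1]
        add(cage_of[[sid]], sid, "counter_reset", t_s[k], t_s[k + 1], "warning")
        d <- pmax(d, 0L)
      }
      r <- rle(d == 0)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in which(r$values)) {
        idx <- starts[j]:ends[j] # increment indices, interval (t[idx], t[idx+1]]
        flat_s <- if (dark_only) sum(phase[idx] == "dark") * period else length(idx) * period
        if (flat_s >= flatline_window_s) {
          others_active <- any(vapply(
            setdiff(scan_ids, sid),
            function(o) sum(inc[[o]][idx]) > 0, logical(1)
          ))
          add(cage_of[[sid]], sid, "flatline",
              t_s[starts[j]], t_s[ends[j] + 1],
              if (others_active) "exclude" else "warning")
        }
      }
    }
  }

  out <- if (length(findings)) dplyr::bind_rows(findings) else tibble::tibble(
    cage = character(), sensor_id = character(), kind = character(),
    start_s = numeric(), end_s = numeric(), severity = character()
  )
  attr(out, "excluded_cages") <- unique(out$cage[out$severity == "exclude"])
  class(out) <- c("qc_report", class(out))
  out
}

#' Cages a QC report recommends excluding
#' @param report A `qc_report` from [qc_scan()].
#' @return Character vector of cage labels.
#' @export
excluded_cages <- function(report) {
  attr(report, "excluded_cages") %||% character()
}

#' Write a QC report as CSV
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), path)
  invisible(path)
}
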