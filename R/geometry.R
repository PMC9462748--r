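#' Wheel geometry
#'
#' Describes the circular path travelled by the magnet glued to the running
#' wheel. One full rotation of the wheel moves the cage occupant by one
#' `circumference_cm`, so all distance conversion in the package reduces to
#' `count * circumference_cm`. Angled running discs used with home-cage huts
#' are typically 15--20 cm in diameter; there is deliberately no default:
#' the experiment configuration must state the geometry.
#'
#' @param magnet_path_diameter_cm Diameter (cm) of the magnet's circular
#'   path. May be omitted when `circumference_cm` is given.
#' @param circumference_cm Circumference (cm); defaults to
#'   `pi * magnet_path_diameter_cm`.
#' @return A `wheel_geometry` object (list with `magnet_path_diameter_cm`
#'   and `circumference_cm`).
#' @examples
#' wheel_geometry(15.9)                    # circumference ~ 50 cm
#' wheel_geometry(circumference_cm = 50)
#' @export
wheel_geometry <- function(magnet_path_diameter_cm = NULL,
                           circumference_cm = NULL) {
  if (is.null(magnet_path_diameter_cm) && is.null(circumference_cm)) {
    validation_error("wheel_geometry() needs a diameter or a circumference; there is no default wheel size.")
  }
  if (is.null(circumference_cm)) {
    circumference_cm <- pi * magnet_path_diameter_cm
  }
  if (is.null(magnet_path_diameter_cm)) {
    magnet_path_diameter_cm <- circumference_cm / pi
  }
  if (!is.numeric(magnet_path_diameter_cm) || magnet_path_diameter_cm <= 0 ||
      !is.numeric(circumference_cm) || circumference_cm <= 0) {
    validation_error("Wheel diameter and circumference must be positive numbers.")
  }
  structure(
    list(
      magnet_path_diameter_cm = as.numeric(magnet_path_diameter_cm),
      circumference_cm = as.numeric(circumference_cm)
    ),
    class = "wheel_geometry"
  )
}

#' @export
print.wheel_geometry <- function(x, ...) {
  cat(sprintf(
    "<wheel_geometry> magnet path diameter %.2f cm, circumference %.2f cm\n",
    x$magnet_path_diameter_cm, x$circumference_cm
  ))
  invisible(x)
}

parse_clock <- function(x) {
  # "HH:MM" or "HH:MM:SS" -> seconds of day
  if (is.numeric(x)) {
    if (x < 0 || x >= 86400) validation_error("Clock time in seconds must lie in [0, 86400).")
    return(as.numeric(x))
  }
  parts <- suppressWarnings(as.numeric(strsplit(x, ":", fixed = TRUE)[[1]]))
  if (length(parts) < 2 || length(parts) > 3 || anyNA(parts)) {
    validation_error(sprintf("Cannot parse clock time %s; use \"HH:MM\" or \"HH:MM:SS\".", deparse(x)))
  }
  if (length(parts) == 2) parts <- c(parts, 0)
  s <- parts[1] * 3600 + parts[2] * 60 + parts[3]
  if (s < 0 || s >= 86400) validation_error("Clock time out of range.")
  s
}

#' Light/dark schedule
#'
#' A 24 h periodic facility lighting schedule. Laboratory mice are nocturnal,
#' so most voluntary running is expected between `dark_onset` and
#' `dark_offset`. The default is a 12 h/12 h cycle with lights off at 19:00.
#'
#' @param dark_onset,dark_offset Clock times (`"HH:MM"`, `"HH:MM:SS"` or
#'   seconds of day) at which the dark phase begins and ends. Must differ.
#' @return A `light_dark_schedule` object.
#' @examples
#' light_dark_schedule("19:00", "07:00")
#' @export
light_dark_schedule <- function(dark_onset = "19:00", dark_offset = "07:00") {
  on <- parse_clock(dark_onset)
  off <- parse_clock(dark_offset)
  if (on == off) validation_error("dark_onset and dark_offset must differ.")
  structure(
    list(dark_onset_s = on, dark_offset_s = off),
    class = "light_dark_schedule"
  )
}

#' @export
print.light_dark_schedule <- function(x, ...) {
  fmt <- function(s) sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)
  cat(sprintf(
    "<light_dark_schedule> dark %s-%s (%.1f h dark)\n",
    fmt(x$dark_onset_s), fmt(x$dark_offset_s),
    ((x$dark_offset_s - x$dark_onset_s) %% 86400) / 3600
  ))
  invisible(x)
}

as_wall_start <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"
  ))
  if (is.na(out)) validation_error(sprintf("Cannot parse wall-clock timestamp %s.", deparse(x)))
  out
}

format_wall_start <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

seconds_of_day <- function(wall_start) {
  as.numeric(wall_start) %% 86400
}

#' Classify time offsets as light or dark phase
#'
#' @param time_s Numeric vector of offsets (s) from `wall_start`.
#' @param wall_start Absolute timestamp (POSIXct or ISO-8601 string, UTC) of
#'   offset zero.
#' @param schedule A [light_dark_schedule()].
#' @return Character vector, `"light"` or `"dark"`, same length as `time_s`.
#' @examples
#' sched <- light_dark_schedule("19:00", "07:00")
#' phase_at(c(0, 3600 * 13), "2022-01-01T19:00:00Z", sched)
#' @export
phase_at <- function(time_s, wall_start, schedule) {
  stopifnot(inherits(schedule, "light_dark_schedule"))
  sod <- (seconds_of_day(as_wall_start(wall_start)) + time_s) %% 86400
  on <- schedule$dark_onset_s
  off <- schedule$dark_offset_s
  dark <- if (on < off) sod >= on & sod < off else sod >= on | sod < off
  ifelse(dark, "dark", "light")
}

dark_fraction_of_day <- function(schedule) {
  ((schedule$dark_offset_s - schedule$dark_onset_s) %% 86400) / 86400
}
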