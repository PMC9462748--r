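phase_rects <- function(series) {
  if (all(is.na(series$phase))) return(NULL)
  r <- rle(series$phase)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(
    phase = r$values,
    xmin = series$time_s[starts] / 3600,
    xmax = series$time_s[ends] / 3600
  )
}

#' Plot an activity series in the light/dark actogram style
#'
#' Cumulative distance (km) and smoothed velocity (cm/s) against time, with
#' dark-phase intervals shaded.
#'
#' @param object An `activity_series` (see [counts_to_activity()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot activity_series
#' @export
autoplot.activity_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(time_h = df$time_s / 3600, value = df$distance_cm / 1e5,
                   metric = "distance (km)"),
    tibble::tibble(time_h = df$time_s / 3600, value = df$velocity_smooth,
                   metric = "smoothed velocity (cm/s)")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value))
  rects <- phase_rects(object)
  if (!is.null(rects)) {
    dark <- rects[rects$phase == "dark", ]
    if (nrow(dark)) {
      p <- p + ggplot2::geom_rect(
        data = dark, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
        fill = "grey35", alpha = 0.25
      )
    }
  }
  p +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = sprintf("Wheel activity, sensor %s", attr(object, "sensor_id"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.activity_series
#' @param series An `activity_series`.
#' @export
plot_activity <- function(series, ...) autoplot.activity_series(series, ...)

#' Plot the permutation null distribution
#'
#' Histogram of the Monte-Carlo null means with the observed statistic as a
#' vertical line; the tail beyond it is what the p-value measures.
#'
#' @param object A `perm_test` (see [permutation_test()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "null mean difference (cm)", y = "permutations",
      title = sprintf("Sign-flip null (B = %d), p = %.4g (%s)",
                      object$n_permutations, object$p_value, object$estimator)
    ) +
    ggplot2::theme_minimal()
}
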