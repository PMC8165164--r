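#' Posterior condition-difference ribbons
#'
#' Posterior mean of the time-varying condition difference in orientation
#' index with its pointwise 95% credible band, one panel per comparison;
#' stretches where the band excludes zero are the difference periods.
#'
#' @param delta_bins tibble with `bin_time`, `delta_mean`, `ci_low`,
#'   `ci_high` and (optionally) `comparison` (as written by [run_pipeline()]
#'   or taken from a `condition_posterior`'s `delta_bins` element).
#' @return A ggplot object.
#' @export
plot_condition_difference <- function(delta_bins) {
  if (!"comparison" %in% names(delta_bins)) delta_bins$comparison <- "difference"
  ggplot2::ggplot(delta_bins, ggplot2::aes(x = bin_time, y = .data$delta_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~comparison, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "orientation-index difference") +
    ggplot2::theme_minimal()
}

#' Mean orientation time course per condition
#'
#' @param binned output of [bin_series()].
#' @return A ggplot object.
#' @export
plot_orientation_timecourse <- function(binned) {
  ggplot2::ggplot(dplyr::filter(binned, !is.na(mean)),
                  ggplot2::aes(x = bin_time, y = mean, colour = condition)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "mean orientation index") +
    ggplot2::theme_minimal()
}

#' Activity rates per condition
#'
#' Per-session log activity rates with condition means and standard errors.
#'
#' @param sessions session-stats tibble from [analyze_sessions()].
#' @return A ggplot object.
#' @export
plot_activity <- function(sessions) {
  s <- dplyr::filter(sessions, !is.na(log_activity))
  ms <- s |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(log_activity),
                     sem = sd(log_activity) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = condition, y = log_activity)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 1) +
    ggplot2::geom_pointrange(data = ms,
                             ggplot2::aes(y = .data$m, ymin = .data$m - .data$sem,
                                          ymax = .data$m + .data$sem),
                             colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "log activity rate (log cm/s)") +
    ggplot2::theme_minimal()
}
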