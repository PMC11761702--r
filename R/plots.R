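# ggplot2 views of the main result types.

#' Plot group learning curves
#'
#' Mean successes (or success rate) per group across days, with SEM
#' error bars, computed by [success_summary()].
#'
#' @param table a learning tibble.
#' @param response `"successes"` or `"rate"`.
#' @return A ggplot.
#' @export
plot_learning_curve <- function(table, response = c("successes", "rate")) {
  response <- match.arg(response)
  sm <- success_summary(table)
  if (response == "successes") {
    sm$m <- sm$mean_successes; sm$s <- sm$sem_successes
    ylab <- "successful reaches"
  } else {
    sm$m <- sm$mean_rate; sm$s <- sm$sem_rate
    ylab <- "success rate"
  }
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$day, y = .data$m,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$s,
                                          ymax = .data$m + .data$s)) +
    ggplot2::scale_x_continuous(trans = "log",
                                breaks = unique(sm$day)) +
    ggplot2::labs(x = "training day (log scale)", y = ylab,
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-correlation trace with detected grabs
#'
#' @param corr output of [sliding_correlation()].
#' @param events optional output of [detect_grabs()]; detected peaks are
#'   marked, the final grab highlighted.
#' @return A ggplot.
#' @export
plot_correlation_trace <- function(corr, events = NULL) {
  p <- ggplot2::ggplot(corr, ggplot2::aes(x = .data$frame,
                                          y = .data$correlation)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "frame", y = "template correlation") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_point(data = events,
                                 ggplot2::aes(y = .data$score,
                                              shape = .data$is_final),
                                 colour = "firebrick", size = 2.5) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 17),
                                  name = "final grab")
  }
  p
}

#' Plot a recruitment curve
#'
#' Median MEP amplitude against stimulation intensity (% of motor
#' threshold), log-scaled amplitude axis.
#'
#' @param curve output of [recruitment_curve()] or [mep_amplitude()].
#' @return A ggplot.
#' @export
plot_recruitment_curve <- function(curve) {
  dat <- curve[!is.na(curve$median_mv), ]
  grp <- intersect("hemisphere", names(dat))
  aes <- if (length(grp)) {
    ggplot2::aes(x = .data$intensity, y = .data$median_mv,
                 colour = .data$hemisphere)
  } else {
    ggplot2::aes(x = .data$intensity, y = .data$median_mv)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "stimulation intensity (% motor threshold)",
                  y = "MEP amplitude (mV, median of trials)") +
    ggplot2::theme_minimal()
}

#' Plot field magnitude against current with the fitted gain
#'
#' Per-frequency points and the through-origin gain line.
#'
#' @param fit a `gain_fit` from [fit_gain()].
#' @return A ggplot.
#' @export
plot_gain_fit <- function(fit) {
  pts <- tidyr::unnest(fit[, c("frequency_hz", "estimates")], "estimates")
  lines <- fit[, c("frequency_hz", "gain")]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$current_ua,
                                    y = .data$magnitude)) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = 0, slope = .data$gain),
                         linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~frequency_hz, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "current (uA)", y = "field magnitude (V/m)") +
    ggplot2::theme_minimal()
}
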