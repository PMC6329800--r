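#' Plot a sliding-window encoding map
#'
#' Correlation coefficient against window center time, with significant
#' windows highlighted and the outcome event marked. For display the map can
#' be smoothed with a Gaussian kernel (SD 25 ms) — smoothing is visual only
#' and never enters any statistic.
#'
#' @param object An `encoding_map`.
#' @param alpha Significance level used for highlighting.
#' @param smooth_sd Gaussian display smoothing SD (s); 0 disables.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.encoding_map <- function(object, alpha = 0.05, smooth_sd = 0, ...) {
  df <- tibble::as_tibble(object)
  if (smooth_sd > 0) df$r <- gauss_smooth(df$time, df$r, smooth_sd)
  df$significant <- !is.na(df$p) & df$p < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant), size = 1.5) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3")) +
    ggplot2::labs(
      x = "time from outcome (s)", y = "rank correlation R",
      title = paste0(attr(object, "regressor"), " encoding map"),
      color = paste0("p < ", alpha)
    ) +
    ggplot2::theme_minimal()
}

gauss_smooth <- function(t, y, sd) {
  vapply(seq_along(t), function(i) {
    w <- exp(-(t - t[i])^2 / (2 * sd^2))
    sum(w * y, na.rm = TRUE) / sum(w[!is.na(y)])
  }, numeric(1))
}

#' Plot normalized cumulative latency distributions
#'
#' Cumulative fraction of encoded windows over time per group, with the
#' quantile crossings marked (the "25% points").
#'
#' @param object A [latency_distribution()].
#' @param q Quantile crossing to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.latency_distribution <- function(object, q = 0.25, ...) {
  df <- tibble::as_tibble(object)
  cross <- latency_quantile(object, q)
  marks <- tibble::tibble(group = names(cross), time = unname(cross), cum = q)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$cum,
    color = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = marks, shape = 1, size = 3) +
    ggplot2::geom_hline(yintercept = q, linetype = 3) +
    ggplot2::labs(
      x = "time from outcome (s)", y = "normalized cumulative sum",
      color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Block-aligned learning curve
#'
#' Proportion correct by trial-within-block, averaged over blocks.
#'
#' @param session A `session_behavior` or `session_set`.
#' @param max_trial Truncate at this trial within block.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(session, max_trial = 30) {
  df <- session$trials |>
    dplyr::filter(.data$trial < max_trial) |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      p_correct = mean(.data$rewarded), n = dplyr::n(),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$p_correct)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "trial after reversal", y = "proportion correct"
    ) +
    ggplot2::theme_minimal()
}

#' Plot color-tuning indices per area
#'
#' Observed index with the randomization null interval per area.
#'
#' @param tuning A [tuning_index_area_test()] result.
#' @return A ggplot object.
#' @export
plot_tuning_index <- function(tuning) {
  ggplot2::ggplot(tuning, ggplot2::aes(x = .data$area, y = .data$i_col)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      width = 0.2, color = "grey50"
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant), size = 3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "red3")) +
    ggplot2::labs(x = NULL, y = "color-tuning index") +
    ggplot2::theme_minimal()
}

#' Plot waveform templates or recorded waveforms
#'
#' @param waveforms List (or single vector) of waveforms.
#' @param labels Optional class labels for coloring.
#' @return A ggplot object.
#' @export
plot_waveforms <- function(waveforms, labels = NULL) {
  if (is.numeric(waveforms)) waveforms <- list(waveforms)
  df <- dplyr::bind_rows(lapply(seq_along(waveforms), function(i) {
    w <- waveforms[[i]]
    dt <- attr(w, "dt") %||% 25e-6
    tibble::tibble(
      unit = i, t_ms = (seq_along(w) - 1) * dt * 1e3,
      v = as.numeric(w),
      class = if (is.null(labels)) "unit" else labels[i]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$t_ms, y = .data$v,
    group = .data$unit, color = .data$class
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "normalized amplitude", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
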