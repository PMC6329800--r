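#' Sliding-window binning configuration
#'
#' Firing rates are analysed in sliding windows aligned to a trial event:
#' window length 200 ms stepped by 25 ms across -500 to +1500 ms around the
#' outcome (73 windows with the defaults). A window is *post-event* if it
#' lies entirely at or after the event and *pre-event* if entirely before;
#' windows straddling the event belong to neither for the run rules. Windows
#' are labelled by their center time.
#'
#' @param event Name of the alignment-event column in the trial table.
#' @param window Window length (s).
#' @param step Window step (s); must divide `window`.
#' @param range Analysis range around the event (s); windows start at
#'   `range[1]` and the last window ends at `range[2]`.
#' @return A list of class `binning_config` with the window start times
#'   (`starts`), centers (`times`) and post/pre masks precomputed.
#' @examples
#' length(binning_config()$starts) # 73
#' @export
binning_config <- function(event = "t_outcome", window = 0.200, step = 0.025,
                           range = c(-0.500, 1.500)) {
  stopifnot(window > 0, step > 0, step <= window, range[1] < range[2])
  m <- window / step
  if (abs(m - round(m)) > 1e-9) {
    stop("`step` must divide `window`.", call. = FALSE)
  }
  starts <- seq(range[1], range[2] - window, by = step)
  structure(
    list(
      event = event, window = window, step = step, range = range,
      starts = starts, times = starts + window / 2,
      is_post = starts >= 0,
      is_pre = starts + window <= 0
    ),
    class = "binning_config"
  )
}

#' @export
print.binning_config <- function(x, ...) {
  cat(sprintf(
    "<binning_config> %d windows of %.0f ms stepped %.0f ms, %.0f..%.0f ms around %s\n",
    length(x$starts), 1e3 * x$window, 1e3 * x$step,
    1e3 * x$range[1], 1e3 * x$range[2], x$event
  ))
  invisible(x)
}

#' Trial-by-window firing-rate matrix
#'
#' Counts each neuron's spikes in every sliding window aligned to the
#' configured event and converts to rates (count / window length). Uses an
#' elementary-bin decomposition (windows are rolling sums of `window/step`
#' elementary bins), exactly equivalent to counting spikes in
#' `[start, start + window)` per window.
#'
#' @param rec A `neuron_recording` (or a tibble with columns `trial`, `t`).
#' @param trials The trial table the recording is linked to.
#' @param cfg A [binning_config()].
#' @return Numeric matrix (trials x windows, Hz) with attribute `cfg`.
#' @export
bin_rates <- function(rec, trials, cfg = binning_config()) {
  spikes <- if (inherits(rec, "neuron_recording")) rec$spikes else rec
  n_trials <- nrow(trials)
  n_cells <- round((cfg$range[2] - cfg$range[1]) / cfg$step)
  m <- round(cfg$window / cfg$step)
  aligned <- spikes$t - trials[[cfg$event]][spikes$trial]
  cell <- floor((aligned - cfg$range[1]) / cfg$step) + 1L
  keep <- cell >= 1L & cell <= n_cells
  idx <- cell[keep] + (spikes$trial[keep] - 1L) * n_cells
  counts <- matrix(tabulate(idx, n_cells * n_trials), nrow = n_cells)
  # rolling sum of m consecutive elementary bins per window
  cs <- rbind(0, apply(counts, 2, cumsum))
  n_win <- length(cfg$starts)
  win <- cs[seq_len(n_win) + m, , drop = FALSE] - cs[seq_len(n_win), , drop = FALSE]
  rates <- t(win) / cfg$window
  attr(rates, "cfg") <- cfg
  rates
}
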