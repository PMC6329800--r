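#' Simulate one neuron's spike trains for a session
#'
#' Event-locked inhomogeneous Poisson spiking. The rate on each trial is the
#' baseline plus, for every planted signal active on that trial, `gain *
#' regressor` within the signal's window (see [neuron_profile()] for the
#' regressor definitions). All contributions are nonnegative, so the process
#' is simulated exactly by superposing independent Poisson processes. Spikes
#' are generated over `[0, t_outcome + post_pad]` of every trial, in seconds
#' from trial start.
#'
#' @param profile A [neuron_profile()].
#' @param trials Trial table carrying event times and an `rpe` column (see
#'   [rpe_trace()]).
#' @param seed Integer seed.
#' @param post_pad Seconds simulated beyond the outcome event.
#' @return A list of class `neuron_recording`: `id`, `area`, `spikes` (tibble
#'   with `trial` — the row index into `trials` — and spike time `t`),
#'   `waveform`, `profile`.
#' @examples
#' spec <- model_spec("F-DW-Dec", eta = 0.22, beta = 3.55, phi = 0.68, omega = 0.92)
#' sess <- generate_session(task_config(n_blocks = 2), agent_rl(spec), seed = 1)
#' tr <- rpe_trace(spec, sess$trials)
#' rec <- simulate_neuron(neuron_profile("ACC", 5), tr, seed = 2)
#' nrow(rec$spikes)
#' @export
simulate_neuron <- function(profile, trials, seed, post_pad = 2) {
  stopifnot(inherits(profile, "neuron_profile"))
  if (nrow(profile$signals) > 0 && !"rpe" %in% names(trials)) {
    stop("`trials` must carry an `rpe` column (see rpe_trace()).", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(trials)
  t_end <- trials$t_outcome + post_pad

  # baseline spikes over the whole simulated span of each trial
  counts <- rpois(n, profile$baseline_hz * t_end)
  trial_id <- rep.int(seq_len(n), counts)
  times <- runif(sum(counts)) * t_end[trial_id]

  sig <- profile$signals
  for (i in seq_len(nrow(sig))) {
    s <- sig[i, ]
    reg <- signal_regressor(s, trials)
    on <- trials[[s$event]] + s$latency
    off <- pmin(on + s$duration, t_end)
    len <- pmax(off - on, 0)
    lambda <- s$gain * reg * len
    extra <- rpois(n, lambda)
    id2 <- rep.int(seq_len(n), extra)
    times2 <- on[id2] + runif(sum(extra)) * (off[id2] - on[id2])
    trial_id <- c(trial_id, id2)
    times <- c(times, times2)
  }
  o <- order(trial_id, times)
  structure(
    list(
      id = profile$id, area = profile$area,
      spikes = tibble::tibble(trial = trial_id[o], t = times[o]),
      waveform = simulate_waveform(profile$waveform_class, seed = seed + 1L),
      profile = profile
    ),
    class = "neuron_recording"
  )
}

# Per-trial regressor value of a planted signal (0 where inactive).
signal_regressor <- function(s, trials) {
  n <- nrow(trials)
  reg <- switch(s$signal,
    outcome = as.numeric(trials$rewarded),
    pRPE = ifelse(trials$rewarded == 1, trials$rpe, 0),
    nRPE = ifelse(trials$rewarded == 0, -trials$rpe, 0),
    uRPE = abs(trials$rpe),
    transfer = transfer_regressor(trials)
  )
  if (!is.na(s$dimension)) {
    chosen <- trials[[s$dimension]]
    if (s$signal == "transfer") {
      # condition evaluated on the previous trial's choice
      chosen <- dplyr::lag(chosen)
    }
    reg[is.na(chosen) | chosen != s$feature] <- 0
  }
  pmax(reg, 0)
}

# 1 - |previous RPE| for consecutive within-block trial pairs, else 0.
transfer_regressor <- function(trials) {
  same <- dplyr::lag(trials$session) == trials$session &
    dplyr::lag(trials$block) == trials$block
  reg <- ifelse(!is.na(same) & same, pmax(1 - abs(dplyr::lag(trials$rpe)), 0), 0)
  reg[is.na(reg)] <- 0
  reg
}

#' @export
print.neuron_recording <- function(x, ...) {
  cat(sprintf(
    "<neuron_recording> id=%s area=%s, %d spikes over %d trials\n",
    x$id, x$area, nrow(x$spikes), length(unique(x$spikes$trial))
  ))
  invisible(x)
}

#' Define a homogeneous group of synthetic neurons
#'
#' One row of a population configuration: `n` neurons in `area` sharing a
#' planted signal description (or pure noise when `signal` is `NA`). Neuron
#' onset latencies are drawn from `latency + Normal(0, latency_sd)`
#' (truncated at 0) so area-specific latency distributions can be planted.
#'
#' @inheritParams planted_signal
#' @param n Number of neurons in the group.
#' @param area Area label.
#' @param latency_sd SD of the per-neuron latency draw (s).
#' @param baseline_hz Baseline rate; `NA` draws log-normally around 5 Hz.
#' @param waveform_class `"narrow"`, `"broad"`, or `NA` to draw (30% narrow).
#' @return A one-row tibble; `rbind`/`dplyr::bind_rows` rows to build a
#'   population.
#' @export
population_group <- function(n, area = "ACC", signal = NA_character_,
                             dimension = NA_character_, feature = NA_integer_,
                             gain = 0, event = "t_outcome", latency = 0.2,
                             latency_sd = 0, duration = 0.4,
                             baseline_hz = NA_real_,
                             waveform_class = NA_character_) {
  tibble::tibble(
    n = as.integer(n), area = area, signal = signal, dimension = dimension,
    feature = as.integer(feature), gain = gain, event = event,
    latency = latency, latency_sd = latency_sd, duration = duration,
    baseline_hz = baseline_hz, waveform_class = waveform_class
  )
}

#' Simulate a population of neurons with known ground truth
#'
#' Expands a population configuration (rows from [population_group()]) into
#' individual neurons, draws unspecified baselines log-normally (meanlog
#' `log(5)`, sdlog 0.4 — practically always above the 0.5 Hz inclusion
#' floor) and unspecified waveform classes (30% narrow), jitters latencies,
#' and simulates every neuron with [simulate_neuron()].
#'
#' @param groups Tibble of [population_group()] rows.
#' @param trials Trial table with `rpe` (see [rpe_trace()]).
#' @param seed Integer seed; neuron `i` uses `seed + 13 * i`.
#' @param post_pad Passed to [simulate_neuron()].
#' @return List with `recordings` (list of `neuron_recording`) and `truth`
#'   (tibble of every neuron's planted properties; `signal` is `NA` for pure
#'   noise neurons).
#' @export
simulate_population <- function(groups, trials, seed, post_pad = 2) {
  seed <- as.integer(seed)
  set.seed(seed)
  idx <- rep(seq_len(nrow(groups)), groups$n)
  n_total <- length(idx)
  g <- groups[idx, ]
  g$neuron <- seq_len(n_total)
  g$baseline_hz <- ifelse(is.na(g$baseline_hz),
    exp(rnorm(n_total, log(5), 0.4)), g$baseline_hz
  )
  g$waveform_class <- ifelse(is.na(g$waveform_class),
    ifelse(runif(n_total) < 0.3, "narrow", "broad"), g$waveform_class
  )
  g$latency <- pmax(g$latency + rnorm(n_total, 0, g$latency_sd), 0)

  recordings <- lapply(seq_len(n_total), function(i) {
    row <- g[i, ]
    signals <- if (is.na(row$signal)) {
      NULL
    } else {
      planted_signal(
        signal = row$signal, gain = row$gain, dimension = row$dimension,
        feature = row$feature, event = row$event, latency = row$latency,
        duration = row$duration
      )
    }
    prof <- neuron_profile(
      area = row$area, baseline_hz = row$baseline_hz, signals = signals,
      waveform_class = row$waveform_class, id = row$neuron
    )
    simulate_neuron(prof, trials, seed = seed + 13L * i, post_pad = post_pad)
  })
  truth <- g[, c(
    "neuron", "area", "signal", "dimension", "feature", "gain",
    "event", "latency", "duration", "baseline_hz", "waveform_class"
  )]
  list(recordings = recordings, truth = tibble::as_tibble(truth))
}
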