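#' Ground-truth firing profile of a synthetic neuron
#'
#' Describes a simulated neuron: its area, Poisson baseline rate, waveform
#' class, and a table of planted signals. Each planted signal adds
#' `gain * regressor(trial)` spikes/s within `[event + latency, event +
#' latency + duration)` on trials matching its feature condition, where the
#' regressor is the trial outcome (0/1) for `"outcome"`, the RPE on correct
#' trials for `"pRPE"`, minus the RPE on error trials for `"nRPE"` (so firing
#' grows as the RPE becomes more negative), and the absolute RPE on all
#' trials for `"uRPE"`. The `"transfer"` signal models attention transfer: it
#' fires at color onset of trial *n* with gain scaled by `1 - |RPE(n-1)|`
#' when trial *n-1* chose the conditioned feature, emulating neurons whose
#' color response grows once prediction errors have shrunk.
#'
#' @param area Area label (`"ACC"`, `"dlPFC"`, `"CD"`, `"VS"`).
#' @param baseline_hz Baseline firing rate (> 0).
#' @param signals Tibble of planted signals with columns `signal`
#'   (`"outcome"`, `"pRPE"`, `"nRPE"`, `"uRPE"`, `"transfer"`), `dimension`
#'   (`NA` for unconditioned, else `"color"`, `"location"`, `"motion"`),
#'   `feature` (`NA` or 1/2), `gain` (Hz per unit regressor), `event`
#'   (`"t_outcome"` or `"t_color_on"`), `latency` and `duration` (s). Use
#'   [planted_signal()] to build rows. `NULL` means a pure-noise neuron.
#' @param waveform_class `"narrow"` or `"broad"`.
#' @param id Neuron identifier.
#' @return A list of class `neuron_profile`.
#' @examples
#' neuron_profile("ACC", 5,
#'   planted_signal("pRPE", gain = 4, dimension = "color", feature = 1)
#' )
#' @export
neuron_profile <- function(area = "ACC", baseline_hz = 5, signals = NULL,
                           waveform_class = c("broad", "narrow"),
                           id = NA_integer_) {
  waveform_class <- match.arg(waveform_class)
  stopifnot(baseline_hz > 0)
  if (is.null(signals)) {
    signals <- planted_signal()[0, ]
  }
  stopifnot(all(signals$duration > 0))
  structure(
    list(
      id = id, area = area, baseline_hz = baseline_hz,
      signals = signals, waveform_class = waveform_class
    ),
    class = "neuron_profile"
  )
}

#' @rdname neuron_profile
#' @param signal,dimension,feature,gain,event,latency,duration See `signals`.
#' @export
planted_signal <- function(signal = "pRPE", gain = 4, dimension = NA_character_,
                           feature = NA_integer_, event = "t_outcome",
                           latency = 0.2, duration = 0.4) {
  stopifnot(signal %in% c("outcome", "pRPE", "nRPE", "uRPE", "transfer"))
  tibble::tibble(
    signal = signal, dimension = dimension,
    feature = as.integer(feature), gain = gain, event = event,
    latency = latency, duration = duration
  )
}

#' @export
print.neuron_profile <- function(x, ...) {
  cat(sprintf(
    "<neuron_profile> id=%s area=%s baseline=%.1f Hz, %s waveform, %d planted signal(s)\n",
    x$id, x$area, x$baseline_hz, x$waveform_class, nrow(x$signals)
  ))
  invisible(x)
}
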