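#' Simulate an extracellular action-potential waveform
#'
#' Biphasic template (negative trough followed by a positive peak) built from
#' two Gaussian lobes on a 25 microsecond grid (40 kHz digitization), with
#' class-dependent trough-to-peak duration and post-peak repolarization:
#' narrow-spiking templates (putative interneurons) have a 0.175 ms
#' trough-to-peak gap and fast repolarization; broad-spiking templates
#' (putative pyramidal cells / medium spiny neurons) have a 0.5 ms gap and
#' slow repolarization. Waveforms are normalized to trough depth 1; `noise_sd`
#' adds white sample noise.
#'
#' @param class `"narrow"` or `"broad"`.
#' @param seed Integer seed (only used when `noise_sd > 0`); `NULL` leaves
#'   the RNG untouched.
#' @param noise_sd White-noise SD in trough-depth units; 0 gives the pure
#'   template.
#' @param n_samples Samples per waveform (64 at 25 us spans 1.575 ms, long
#'   enough to contain the broad template's repolarization).
#' @param dt Sampling step in seconds.
#' @return Numeric waveform with attributes `dt` and `class`.
#' @examples
#' w <- simulate_waveform("narrow", noise_sd = 0)
#' extract_waveform_features(w)
#' @export
simulate_waveform <- function(class = c("broad", "narrow"), seed = NULL,
                              noise_sd = 0.02, n_samples = 64L, dt = 25e-6) {
  class <- match.arg(class)
  if (!is.null(seed) && noise_sd > 0) set.seed(as.integer(seed))
  p <- waveform_params(class)
  t <- (seq_len(n_samples) - 1) * dt * 1e3 # ms
  w <- -exp(-(t - p$t_trough)^2 / (2 * p$sd_trough^2)) +
    p$peak_amp * exp(-(t - p$t_trough - p$trough_to_peak)^2 / (2 * p$sd_peak^2))
  if (noise_sd > 0) w <- w + rnorm(n_samples, 0, noise_sd)
  structure(w, dt = dt, class_label = class)
}

# Template geometry (ms). Lobes are narrow relative to their separation so
# grid extrema sit exactly at the configured centers.
waveform_params <- function(class) {
  if (class == "narrow") {
    list(
      t_trough = 0.25, trough_to_peak = 0.175,
      sd_trough = 0.035, sd_peak = 0.05, peak_amp = 0.45
    )
  } else {
    list(
      t_trough = 0.25, trough_to_peak = 0.5,
      sd_trough = 0.09, sd_peak = 0.15, peak_amp = 0.55
    )
  }
}

#' Extract waveform shape features
#'
#' Landmarks are computed on a spline-interpolated waveform (upsampled 16x).
#' Cortical features: trough-to-peak duration and time to repolarization
#' (time from the peak back down to `repol_frac` of peak amplitude).
#' Striatal features: trough width at half amplitude and the initial slope
#' of valley decay (ISVD) — the recovery slope of the trough-normalized
#' waveform over the first `isvd_window` ms after the trough. Monophasic
#' waveforms (no positive peak after the trough) yield `NA` features and are
#' later labelled "unidentified".
#'
#' @param waveform Numeric waveform (see [simulate_waveform()]); amplitude
#'   scaling does not affect any time-based feature.
#' @param region `"cortical"` or `"striatal"` feature set (both are always
#'   computed; the region only records intent).
#' @param dt Sampling step (s); taken from the waveform attribute if present.
#' @param repol_frac Repolarization threshold as a fraction of peak amplitude.
#' @param isvd_window ISVD slope window after the trough (ms).
#' @return One-row tibble: `duration_ms`, `repol_ms`, `trough_width_ms`,
#'   `isvd`, `ok`.
#' @export
extract_waveform_features <- function(waveform, region = c("cortical", "striatal"),
                                      dt = NULL, repol_frac = 0.25,
                                      isvd_window = 0.1) {
  region <- match.arg(region)
  if (is.null(dt)) dt <- attr(waveform, "dt") %||% 25e-6
  w <- as.numeric(waveform)
  t <- (seq_along(w) - 1) * dt * 1e3 # ms
  # upsample for sub-sample landmarks
  up <- spline(t, w, n = length(w) * 16L)
  ti <- up$x
  wi <- up$y

  i_tr <- which.min(wi)
  after <- seq(i_tr, length(wi))
  i_pk <- after[which.max(wi[after])]
  peak <- wi[i_pk]
  trough <- wi[i_tr]
  # a genuine positive peak must rise above interpolation ripple
  if (i_pk <= i_tr || peak <= 0.05 * abs(trough)) {
    return(tibble::tibble(
      duration_ms = NA_real_, repol_ms = NA_real_,
      trough_width_ms = NA_real_, isvd = NA_real_, ok = FALSE
    ))
  }
  duration <- ti[i_pk] - ti[i_tr]

  # time from peak to repol_frac * peak
  post <- seq(i_pk, length(wi))
  below <- post[wi[post] <= repol_frac * peak]
  repol <- if (length(below)) ti[below[1]] - ti[i_pk] else NA_real_

  # trough width at half amplitude
  half <- trough / 2
  left <- rev(seq_len(i_tr))
  right <- seq(i_tr, length(wi))
  l <- left[wi[left] >= half][1]
  r <- right[wi[right] >= half][1]
  width <- if (!is.na(l) && !is.na(r)) ti[r] - ti[l] else NA_real_

  # initial slope of valley decay on the trough-normalized waveform
  wn <- wi / abs(trough)
  t_end <- ti[i_tr] + isvd_window
  v0 <- wn[i_tr]
  v1 <- approx(ti, wn, xout = t_end)$y
  isvd <- if (!is.na(v1)) (v1 - v0) / isvd_window else NA_real_

  tibble::tibble(
    duration_ms = duration, repol_ms = repol,
    trough_width_ms = width, isvd = isvd, ok = TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
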