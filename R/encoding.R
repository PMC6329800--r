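#' Thresholds of the encoding classifier
#'
#' All decision constants of the classification pipeline, with the study
#' defaults: per-bin significance `alpha = 0.05`, correlation-difference
#' threshold `z_crit = 1.96`, a minimum of `min_run = 4` consecutive
#' significant post-outcome windows (0.1 s at the 25 ms step), at most
#' `max_pre_run = 2` consecutive significant pre-outcome windows, at least
#' `min_trials = 15` trials per correlation, `min_usable_trials = 40` usable
#' trials per neuron, and a `min_rate_hz = 0.5` firing-rate floor within the
#' 0-1.5 s feedback epoch. `nrpe_positive = TRUE` switches to the alternative
#' negative-RPE convention (firing decreasing with more negative RPEs).
#'
#' @param alpha,z_crit,min_run,max_pre_run,min_trials,min_usable_trials,min_rate_hz,nrpe_positive
#'   See description.
#' @return A list of class `encoding_thresholds`.
#' @export
encoding_thresholds <- function(alpha = 0.05, z_crit = 1.96, min_run = 4,
                                max_pre_run = 2, min_trials = 15,
                                min_usable_trials = 40, min_rate_hz = 0.5,
                                nrpe_positive = FALSE) {
  structure(
    list(
      alpha = alpha, z_crit = z_crit, min_run = min_run,
      max_pre_run = max_pre_run, min_trials = min_trials,
      min_usable_trials = min_usable_trials, min_rate_hz = min_rate_hz,
      nrpe_positive = nrpe_positive
    ),
    class = "encoding_thresholds"
  )
}

#' Neuron inclusion decision
#'
#' A neuron enters the encoding analyses iff (i) its mean firing rate within
#' the feedback epoch (0-1.5 s after outcome) is at least `min_rate_hz`,
#' (ii) at least `min_usable_trials` usable trials exist — choice trials of
#' blocks learned to the ideal-observer criterion, with an RPE available —
#' and (iii) learned/unlearned block labelling is possible (at least one
#' learned block). Trials from unlearned blocks are discarded.
#'
#' @param rec A `neuron_recording`.
#' @param trials Trial table with `rpe`.
#' @param blocks Per-block annotations (see [generate_session()]; needs
#'   `session`, `block`, `learned`).
#' @param thresholds An [encoding_thresholds()].
#' @return A list: `include` (logical), `reasons` (character, empty when
#'   included), `usable` (logical mask over trials), `feedback_rate_hz`.
#' @export
include_neuron <- function(rec, trials, blocks,
                           thresholds = encoding_thresholds()) {
  aligned <- rec$spikes$t - trials$t_outcome[rec$spikes$trial]
  n_fb <- sum(aligned >= 0 & aligned < 1.5)
  rate <- n_fb / (1.5 * nrow(trials))

  learned <- blocks[blocks$learned, c("session", "block")]
  usable <- paste(trials$session, trials$block) %in%
    paste(learned$session, learned$block) & !is.na(trials$rpe)

  reasons <- character(0)
  if (rate < thresholds$min_rate_hz) reasons <- c(reasons, "rate")
  if (!any(blocks$learned)) reasons <- c(reasons, "no_learned_blocks")
  if (sum(usable) < thresholds$min_usable_trials) reasons <- c(reasons, "trials")
  list(
    include = length(reasons) == 0, reasons = reasons,
    usable = usable, feedback_rate_hz = rate
  )
}

# Spearman correlation of each rate column with x, p by t-approximation
# (df = n - 2) or by label permutation.
spearman_cols <- function(rates, x, p_method = c("t", "permutation"),
                          n_perm = 999) {
  p_method <- match.arg(p_method)
  n <- length(x)
  r <- suppressWarnings(as.vector(cor(rates, x, method = "spearman")))
  r[is.na(r)] <- 0
  if (p_method == "t") {
    p <- r_to_p(r, n, df_offset = 2)
  } else {
    xr <- rank(x)
    rr <- apply(rates, 2, rank)
    obs <- abs(r)
    hits <- rep(0L, length(r))
    for (b in seq_len(n_perm)) {
      rb <- suppressWarnings(as.vector(cor(rr, sample(xr))))
      rb[is.na(rb)] <- 0
      hits <- hits + (abs(rb) >= obs - 1e-12)
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(r = r, p = p, n = n)
}

r_to_p <- function(r, n, df_offset = 2) {
  df <- n - df_offset
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  tt[r2 >= 1] <- Inf
  2 * pt(-tt, df)
}

new_encoding_map <- function(cfg, r, p, n, regressor, required_sign,
                             evaluable = TRUE, note = NA_character_) {
  out <- tibble::tibble(
    bin = seq_along(cfg$starts),
    time = cfg$times, start = cfg$starts,
    r = if (evaluable) r else NA_real_,
    p = if (evaluable) p else NA_real_,
    n = n
  )
  structure(out,
    class = c("encoding_map", class(out)),
    cfg = cfg, regressor = regressor, required_sign = required_sign,
    evaluable = evaluable, note = note
  )
}

#' Sliding-window correlation of firing rate with RPE
#'
#' Rank (Spearman) correlation of each window's rate with the model RPE:
#' positive RPEs in correct trials (`mode = "pRPE"`, positive correlations
#' count) or negative RPEs in error trials (`mode = "nRPE"`, negative
#' correlations count — firing rises as the RPE grows more negative; set
#' `nrpe_positive` in the thresholds for the opposite convention). Maps with
#' fewer than `min_trials` trials are marked not evaluable.
#'
#' @param rates Trial x window rate matrix from [bin_rates()].
#' @param trials Trial table with `rpe` and `rewarded`.
#' @param mode `"pRPE"` or `"nRPE"`.
#' @param mask Logical mask of trials to use (e.g. usable trials, or a
#'   feature split); combined with the mode's trial class.
#' @param thresholds An [encoding_thresholds()].
#' @param p_method `"t"` (default) or `"permutation"` (recommended for
#'   fewer than ~20 trials).
#' @return An `encoding_map` tibble: one row per window with `time`, `start`,
#'   `r`, `p`, `n`; attributes record the regressor and required sign.
#' @export
rpe_correlation_map <- function(rates, trials, mode = c("pRPE", "nRPE"),
                                mask = NULL,
                                thresholds = encoding_thresholds(),
                                p_method = "t") {
  mode <- match.arg(mode)
  cfg <- attr(rates, "cfg")
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  cls <- if (mode == "pRPE") trials$rewarded == 1 else trials$rewarded == 0
  use <- mask & cls & !is.na(trials$rpe)
  required_sign <- if (mode == "pRPE") {
    1
  } else if (thresholds$nrpe_positive) {
    1
  } else {
    -1
  }
  if (sum(use) < thresholds$min_trials) {
    return(new_encoding_map(cfg, NA, NA, sum(use), mode, required_sign,
      evaluable = FALSE, note = "too few trials"
    ))
  }
  sp <- spearman_cols(rates[use, , drop = FALSE], trials$rpe[use],
    p_method = p_method
  )
  new_encoding_map(cfg, sp$r, sp$p, sp$n, mode, required_sign)
}

#' Sliding-window partial correlation with unsigned RPE (surprise)
#'
#' Partial rank correlation of each window's rate with `|RPE|` across both
#' correct and error trials, controlling for outcome sign via a +/-1
#' covariate (computed as Pearson partial correlation on ranks; p by
#' t-approximation with df = n - 3). If the covariate is constant in the
#' masked trials the map reduces to a plain rank correlation and the
#' attribute `note` says so.
#'
#' @inheritParams rpe_correlation_map
#' @return An `encoding_map` (regressor `"uRPE"`, positive correlations
#'   count).
#' @export
unsigned_rpe_map <- function(rates, trials, mask = NULL,
                             thresholds = encoding_thresholds()) {
  cfg <- attr(rates, "cfg")
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  use <- mask & !is.na(trials$rpe)
  if (sum(use) < thresholds$min_trials) {
    return(new_encoding_map(cfg, NA, NA, sum(use), "uRPE", 1,
      evaluable = FALSE, note = "too few trials"
    ))
  }
  x <- abs(trials$rpe[use])
  z <- ifelse(trials$rewarded[use] == 1, 1, -1)
  rr <- apply(rates[use, , drop = FALSE], 2, rank)
  xr <- rank(x)
  n <- length(xr)
  if (length(unique(z)) == 1) {
    sp <- list(
      r = fix_na(as.vector(suppressWarnings(cor(rr, xr)))),
      p = NULL, n = n
    )
    p <- r_to_p(sp$r, n, df_offset = 2)
    return(new_encoding_map(cfg, sp$r, p, n, "uRPE", 1,
      note = "constant covariate; plain rank correlation"
    ))
  }
  zr <- rank(z)
  r_xy <- fix_na(as.vector(suppressWarnings(cor(rr, xr))))
  r_xz <- fix_na(as.vector(suppressWarnings(cor(rr, zr))))
  r_yz <- fix_na(suppressWarnings(cor(xr, zr)))
  den <- sqrt(pmax((1 - r_xz^2) * (1 - r_yz^2), .Machine$double.eps))
  rp <- (r_xy - r_xz * r_yz) / den
  rp <- pmin(pmax(fix_na(rp), -1), 1)
  p <- r_to_p(rp, n, df_offset = 3)
  new_encoding_map(cfg, rp, p, n, "uRPE", 1)
}

fix_na <- function(x) {
  x[is.na(x)] <- 0
  x
}

#' Outcome (reward vs no-reward) encoding
#'
#' Linear regression of the mean firing rate in 0.1-0.7 s after outcome on
#' the rewarded indicator; the neuron is flagged when the slope is
#' significant at `alpha`. A per-window regression map (slope sign as the
#' correlation sign) is also returned so that outcome latencies can use the
#' same consecutive-run rule as the RPE signals.
#'
#' @inheritParams rpe_correlation_map
#' @param window Epoch (s after outcome) for the summary regression.
#' @return A list: `flagged`, `slope`, `p`, `n`, and `map` (an
#'   `encoding_map` of per-window rate-vs-outcome rank correlations,
#'   two-sided).
#' @export
outcome_encoding <- function(rates, trials, mask = NULL,
                             window = c(0.1, 0.7),
                             thresholds = encoding_thresholds()) {
  cfg <- attr(rates, "cfg")
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  y <- trials$rewarded[mask]
  if (length(unique(y)) < 2) {
    return(list(
      flagged = NA, slope = NA_real_, p = NA_real_, n = sum(mask),
      map = new_encoding_map(cfg, NA, NA, sum(mask), "outcome", 0,
        evaluable = FALSE, note = "single outcome class"
      )
    ))
  }
  cover <- cfg$starts >= window[1] & (cfg$starts + cfg$window) <= window[2]
  mean_rate <- rowMeans(rates[mask, cover, drop = FALSE])
  fit <- lm(mean_rate ~ y)
  sm <- summary(fit)$coefficients
  slope <- sm["y", "Estimate"]
  p <- sm["y", "Pr(>|t|)"]
  sp <- spearman_cols(rates[mask, , drop = FALSE], y)
  map <- new_encoding_map(cfg, sp$r, sp$p, sp$n, "outcome", 0)
  list(
    flagged = p < thresholds$alpha, slope = slope, p = p, n = length(y),
    map = map
  )
}

#' Detect an encoding window in a correlation map
#'
#' A signal is encoded iff the map has at least `min_run` consecutive
#' significant windows of the required correlation sign among the
#' post-outcome windows, while no run of more than `max_pre_run` significant
#' same-sign windows exists among the pre-outcome windows. The reported
#' encoding window is the first qualifying run (in full).
#'
#' @param map An `encoding_map`.
#' @param thresholds An [encoding_thresholds()].
#' @return One-row tibble: `encodes`, `evaluable`, `window_start_s` (start
#'   time of the first window in the run), `window_len_s` (time covered by
#'   the run), `r_peak` (signed extreme correlation within the run),
#'   `first_run_times` and `all_sig_times` (list-columns of window center
#'   times, for latency pooling).
#' @export
detect_encoding <- function(map, thresholds = encoding_thresholds()) {
  cfg <- attr(map, "cfg")
  empty <- tibble::tibble(
    encodes = FALSE, evaluable = attr(map, "evaluable"),
    window_start_s = NA_real_, window_len_s = NA_real_, r_peak = NA_real_,
    first_run_times = list(numeric(0)), all_sig_times = list(numeric(0))
  )
  if (!attr(map, "evaluable")) {
    return(empty)
  }
  required_sign <- attr(map, "required_sign")
  sig <- map$p < thresholds$alpha &
    (if (required_sign == 0) TRUE else sign(map$r) == required_sign)
  sig[is.na(sig)] <- FALSE

  pre_max <- max_run(sig[cfg$is_pre])
  post_idx <- which(cfg$is_post)
  runs <- run_spans(sig[post_idx])
  runs <- runs[runs$length >= thresholds$min_run, , drop = FALSE]
  if (nrow(runs) == 0 || pre_max > thresholds$max_pre_run) {
    out <- empty
    out$all_sig_times <- list(map$time[post_idx][sig[post_idx]])
    return(out)
  }
  first <- post_idx[seq(runs$start[1], runs$end[1])]
  tibble::tibble(
    encodes = TRUE, evaluable = TRUE,
    window_start_s = cfg$starts[first[1]],
    window_len_s = (length(first) - 1) * cfg$step + cfg$window,
    r_peak = map$r[first][which.max(abs(map$r[first]))],
    first_run_times = list(map$time[first]),
    all_sig_times = list(map$time[post_idx][sig[post_idx]])
  )
}

max_run <- function(x) {
  if (!length(x) || !any(x)) {
    return(0L)
  }
  r <- rle(x)
  max(r$lengths[r$values])
}

run_spans <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts, end = ends, length = r$lengths)[r$values, ,
    drop = FALSE
  ]
}

#' Fisher z-test for the difference of two correlations
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(N1-3) + 1/(N2-3))`; the difference
#' is significant at p < 0.05 when `|Z| > 1.96`. Vectorized over windows.
#'
#' @param r1,r2 Correlation coefficients (strictly inside (-1, 1)).
#' @param n1,n2 Sample sizes (> 3).
#' @return Numeric Z values.
#' @examples
#' fisher_z_compare(0.5, 103, 0, 103) # ~ 3.88
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (any(c(n1, n2) <= 3)) {
    stop("Sample sizes must exceed 3.", call. = FALSE)
  }
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("Correlations must lie strictly inside (-1, 1).", call. = FALSE)
  }
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}
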