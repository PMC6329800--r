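#' Select extreme-RPE trials
#'
#' Picks the lowest and highest quarter of eligible trials by absolute RPE
#' for one signal type (correct trials for pRPE, error trials for nRPE, all
#' choice trials for uRPE). Each set contains `floor(fraction * n)` trials;
#' ties are broken by trial order.
#'
#' @param trials Trial table with `rpe`.
#' @param signal `"pRPE"`, `"nRPE"` or `"uRPE"`.
#' @param mask Optional logical mask of usable trials.
#' @param fraction Fraction per extreme set.
#' @param min_trials Minimum eligible trials; fewer returns `NULL` (neuron
#'   skipped).
#' @return A list with `low` and `high` (integer row indices into `trials`,
#'   trial *n* of each pair) or `NULL`.
#' @export
select_extreme_rpe_trials <- function(trials, signal, mask = NULL,
                                      fraction = 0.25, min_trials = 8) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  cls <- switch(signal,
    pRPE = trials$rewarded == 1,
    nRPE = trials$rewarded == 0,
    uRPE = rep(TRUE, nrow(trials)),
    stop("Unknown signal type: ", signal, call. = FALSE)
  )
  eligible <- which(mask & cls & !is.na(trials$rpe))
  if (length(eligible) < min_trials) {
    return(NULL)
  }
  k <- floor(fraction * length(eligible))
  mag <- abs(trials$rpe[eligible])
  ord <- order(mag, eligible) # ties broken by trial order
  list(
    low = sort(eligible[ord[seq_len(k)]]),
    high = sort(eligible[rev(ord)[seq_len(k)]])
  )
}

#' Normalized color-onset rate change on follow-up trials
#'
#' For each selected trial *n*, takes the next trial *n + 1* (only
#' consecutive pairs within the same block are used) and computes the
#' normalized firing-rate change around its color onset: `delta =
#' (r_post - r_pre) / (r_post + r_pre)`, defined 0 when both rates are 0, so
#' `delta` ranges over `[-1, 1]` and is invariant to rate scaling.
#'
#' @param rec A `neuron_recording`.
#' @param trials Trial table.
#' @param rows_n Integer rows of trials *n* (see
#'   [select_extreme_rpe_trials()]).
#' @param pre,post Windows (s) around color onset of trial *n + 1*.
#' @return Tibble: `row_n`, `row_n1`, `prev_color` (chosen color on trial
#'   *n*), `delta`.
#' @export
color_onset_rate_change <- function(rec, trials, rows_n,
                                    pre = c(-0.5, 0), post = c(0, 0.5)) {
  n1 <- rows_n + 1L
  ok <- n1 <= nrow(trials) &
    trials$session[rows_n] == trials$session[pmin(n1, nrow(trials))] &
    trials$block[rows_n] == trials$block[pmin(n1, nrow(trials))]
  rows_n <- rows_n[ok]
  n1 <- n1[ok]
  if (!length(rows_n)) {
    return(tibble::tibble(
      row_n = integer(0), row_n1 = integer(0),
      prev_color = integer(0), delta = numeric(0)
    ))
  }
  counts_in <- function(win) {
    ref <- trials$t_color_on[n1]
    vapply(seq_along(n1), function(i) {
      s <- rec$spikes$t[rec$spikes$trial == n1[i]] - ref[i]
      sum(s >= win[1] & s < win[2])
    }, numeric(1))
  }
  r_pre <- counts_in(pre) / diff(pre)
  r_post <- counts_in(post) / diff(post)
  tot <- r_pre + r_post
  delta <- ifelse(tot == 0, 0, (r_post - r_pre) / tot)
  tibble::tibble(
    row_n = rows_n, row_n1 = n1,
    prev_color = trials$color[rows_n], delta = delta
  )
}

#' Per-neuron attention-transfer conditions
#'
#' Combines [select_extreme_rpe_trials()] and [color_onset_rate_change()]
#' into the four transfer conditions of one color-specific RPE neuron: RPE
#' quartile (low/high on trial *n*) crossed with the previous choice being
#' the neuron's preferred or nonpreferred color.
#'
#' @inheritParams color_onset_rate_change
#' @param signal The neuron's RPE signal type.
#' @param preferred_feature The neuron's preferred color (1 or 2).
#' @param mask Optional usable-trial mask.
#' @param fraction Extreme-RPE fraction.
#' @return Tibble with one row per condition: `neuron`, `area`, `rpe_set`,
#'   `prev`, `delta` (mean), `n_pairs`; `NULL` when the neuron has too few
#'   eligible trials.
#' @export
neuron_transfer_deltas <- function(rec, trials, signal, preferred_feature,
                                   mask = NULL, fraction = 0.25,
                                   pre = c(-0.5, 0), post = c(0, 0.5)) {
  sets <- select_extreme_rpe_trials(trials, signal, mask, fraction)
  if (is.null(sets)) {
    return(NULL)
  }
  res <- lapply(c(low = "low", high = "high"), function(s) {
    ch <- color_onset_rate_change(rec, trials, sets[[s]], pre, post)
    ch$rpe_set <- s
    ch
  })
  ch <- dplyr::bind_rows(res)
  if (nrow(ch) == 0) {
    return(NULL)
  }
  ch$prev <- ifelse(ch$prev_color == preferred_feature, "preferred", "nonpreferred")
  ch |>
    dplyr::group_by(.data$rpe_set, .data$prev) |>
    dplyr::summarise(
      delta = mean(.data$delta), n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      neuron = rec$id %||% NA_integer_, area = rec$area %||% NA_character_,
      .before = 1
    )
}

#' Attention-transfer contrast across neurons
#'
#' Paired comparisons of the normalized color-onset rate change following
#' low- versus high-RPE trials, within the preferred and within the
#' nonpreferred previous-color condition, plus a one-sample test that the
#' overall rate change is positive. Effect sizes are Hedges' g.
#'
#' @param deltas Bound [neuron_transfer_deltas()] rows.
#' @param by Optional grouping column (e.g. `"area"`); `NULL` pools all
#'   neurons.
#' @return Tibble: grouping column (if any), `contrast` (`"preferred"`,
#'   `"nonpreferred"`, `"overall_positive"`), `n`, `t`, `p`, `g`,
#'   `evaluable`.
#' @export
transfer_contrast <- function(deltas, by = NULL) {
  groups <- if (is.null(by)) list(all = deltas) else split(deltas, deltas[[by]])
  out <- lapply(names(groups), function(gname) {
    d <- groups[[gname]]
    rows <- lapply(c("preferred", "nonpreferred"), function(cond) {
      wide <- d |>
        dplyr::filter(.data$prev == cond) |>
        tidyr::pivot_wider(
          id_cols = "neuron", names_from = "rpe_set",
          values_from = "delta"
        )
      paired_row(wide, cond)
    })
    overall <- d |>
      dplyr::group_by(.data$neuron) |>
      dplyr::summarise(delta = mean(.data$delta), .groups = "drop")
    rows[[3]] <- one_sample_row(overall$delta, "overall_positive")
    res <- dplyr::bind_rows(rows)
    if (!is.null(by)) res <- dplyr::mutate(res, !!by := gname, .before = 1)
    res
  })
  dplyr::bind_rows(out)
}

paired_row <- function(wide, label) {
  ok <- all(c("low", "high") %in% names(wide))
  if (ok) {
    wide <- wide[complete.cases(wide[, c("low", "high")]), , drop = FALSE]
  }
  diffs <- if (ok) wide$low - wide$high else numeric(0)
  if (length(diffs) < 2 || sd(diffs) == 0) {
    return(tibble::tibble(
      contrast = label, n = length(diffs), t = NA_real_, p = NA_real_,
      g = NA_real_, evaluable = FALSE
    ))
  }
  tt <- t.test(wide$low, wide$high, paired = TRUE)
  tibble::tibble(
    contrast = label, n = length(diffs),
    t = unname(tt$statistic), p = tt$p.value,
    g = hedges_g(diffs), evaluable = TRUE
  )
}

one_sample_row <- function(x, label) {
  if (length(x) < 2 || sd(x) == 0) {
    return(tibble::tibble(
      contrast = label, n = length(x), t = NA_real_, p = NA_real_,
      g = NA_real_, evaluable = FALSE
    ))
  }
  tt <- t.test(x, mu = 0, alternative = "greater")
  tibble::tibble(
    contrast = label, n = length(x), t = unname(tt$statistic), p = tt$p.value,
    g = hedges_g(x), evaluable = TRUE
  )
}

# Hedges' g for a (paired-difference or one-sample) vector.
hedges_g <- function(x) {
  df <- length(x) - 1
  (mean(x) / sd(x)) * (1 - 3 / (4 * df - 1))
}
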