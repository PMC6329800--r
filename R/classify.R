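#' Feature-specific RPE classification for one dimension
#'
#' Splits trials by the chosen feature value of `dimension` (e.g. color 1
#' vs color 2 chosen), computes an RPE correlation map per split, and
#' compares the two maps window-by-window with the Fisher z-test
#' ([fisher_z_compare()]). The neuron is feature-specific for this
#' (signal, dimension) iff (i) at least `min_run` consecutive post-outcome
#' windows show `|Z| > z_crit`, (ii) the encoding criterion
#' ([detect_encoding()]) holds for at least one feature value, and (iii) the
#' z-difference run overlaps that encoding run by at least one window. The
#' preferred feature is the value with the qualifying encoding (the larger
#' peak |R| decides if both encode). Either split having fewer than
#' `min_trials` trials makes the dimension not evaluable.
#'
#' @param rates Trial x window rate matrix ([bin_rates()]).
#' @param trials Trial table with `rpe`, `rewarded` and chosen features.
#' @param dimension `"color"`, `"location"` or `"motion"`.
#' @param mode `"pRPE"`, `"nRPE"` or `"uRPE"`.
#' @param mask Logical mask of usable trials.
#' @param thresholds An [encoding_thresholds()].
#' @return One-row tibble: `dimension`, `signal`, `evaluable`, `specific`,
#'   `preferred_feature`, `window_start_s`, `window_len_s`, `r_peak`, and
#'   latency list-columns of the preferred feature's detection.
#' @export
classify_feature_specific <- function(rates, trials, dimension,
                                      mode = c("pRPE", "nRPE", "uRPE"),
                                      mask = NULL,
                                      thresholds = encoding_thresholds()) {
  mode <- match.arg(mode)
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  chosen <- trials[[dimension]]
  maps <- lapply(1:2, function(f) {
    split_mask <- mask & chosen == f
    if (mode == "uRPE") {
      unsigned_rpe_map(rates, trials, mask = split_mask, thresholds = thresholds)
    } else {
      rpe_correlation_map(rates, trials,
        mode = mode, mask = split_mask,
        thresholds = thresholds
      )
    }
  })
  out <- tibble::tibble(
    dimension = dimension, signal = mode, evaluable = TRUE, specific = FALSE,
    preferred_feature = NA_integer_, window_start_s = NA_real_,
    window_len_s = NA_real_, r_peak = NA_real_,
    first_run_times = list(numeric(0)), all_sig_times = list(numeric(0))
  )
  if (!attr(maps[[1]], "evaluable") || !attr(maps[[2]], "evaluable")) {
    out$evaluable <- FALSE
    return(out)
  }
  cfg <- attr(maps[[1]], "cfg")
  r1 <- clamp_r(maps[[1]]$r)
  r2 <- clamp_r(maps[[2]]$r)
  z <- fisher_z_compare(r1, maps[[1]]$n[1], r2, maps[[2]]$n[1])
  z_sig <- abs(z) > thresholds$z_crit
  post_idx <- which(cfg$is_post)
  z_runs <- run_spans(z_sig[post_idx])
  z_runs <- z_runs[z_runs$length >= thresholds$min_run, , drop = FALSE]
  if (nrow(z_runs) == 0) {
    return(out)
  }
  z_bins <- unlist(lapply(seq_len(nrow(z_runs)), function(i) {
    post_idx[seq(z_runs$start[i], z_runs$end[i])]
  }))

  det <- lapply(maps, detect_encoding, thresholds = thresholds)
  overlaps <- vapply(seq_along(det), function(f) {
    d <- det[[f]]
    if (!d$encodes) {
      return(FALSE)
    }
    run_bins <- which(cfg$times %in% d$first_run_times[[1]])
    length(intersect(run_bins, z_bins)) >= 1
  }, logical(1))
  if (!any(overlaps)) {
    return(out)
  }
  pref <- which(overlaps)
  if (length(pref) == 2) {
    pref <- pref[which.max(c(abs(det[[1]]$r_peak), abs(det[[2]]$r_peak)))]
  }
  d <- det[[pref]]
  out$specific <- TRUE
  out$preferred_feature <- as.integer(pref)
  out$window_start_s <- d$window_start_s
  out$window_len_s <- d$window_len_s
  out$r_peak <- d$r_peak
  out$first_run_times <- d$first_run_times
  out$all_sig_times <- d$all_sig_times
  out
}

clamp_r <- function(r, eps = 1e-7) pmin(pmax(r, -1 + eps), 1 - eps)

#' Classify one neuron's encoding labels
#'
#' Runs the full per-neuron pipeline: inclusion filter, outcome-encoding
#' test, pooled (nonspecific) RPE maps for pRPE/nRPE/uRPE with run-rule
#' detection, and feature-specific classification per (signal, dimension).
#'
#' @param rec A `neuron_recording`.
#' @param trials Trial table with `rpe`.
#' @param blocks Per-block annotations (see [generate_session()]).
#' @param cfg A [binning_config()].
#' @param thresholds An [encoding_thresholds()].
#' @return A tibble of label rows (see [finalize_labels()]) with one row per
#'   (signal, scope, dimension) decision, including non-flagged rows;
#'   attribute `inclusion` carries the [include_neuron()] result.
#' @export
classify_neuron <- function(rec, trials, blocks, cfg = binning_config(),
                            thresholds = encoding_thresholds()) {
  inc <- include_neuron(rec, trials, blocks, thresholds)
  base <- tibble::tibble(
    neuron = rec$id %||% NA_integer_, area = rec$area %||% NA_character_
  )
  if (!inc$include) {
    out <- dplyr::bind_cols(base, tibble::tibble(
      signal = character(0), scope = character(0), dimension = character(0),
      flagged = logical(0), preferred_feature = integer(0),
      window_start_s = numeric(0), window_len_s = numeric(0),
      r_peak = numeric(0), first_run_times = list(), all_sig_times = list()
    )[0, ])[0, ]
    attr(out, "inclusion") <- inc
    return(out)
  }
  mask <- inc$usable
  rates <- bin_rates(rec, trials, cfg)

  rows <- list()
  oc <- outcome_encoding(rates, trials, mask = mask, thresholds = thresholds)
  oc_det <- detect_encoding(oc$map, thresholds = thresholds)
  rows[["outcome"]] <- tibble::tibble(
    signal = "outcome", scope = "nonspecific", dimension = NA_character_,
    flagged = isTRUE(oc$flagged), preferred_feature = NA_integer_,
    window_start_s = oc_det$window_start_s, window_len_s = oc_det$window_len_s,
    r_peak = oc_det$r_peak,
    first_run_times = oc_det$first_run_times,
    all_sig_times = oc_det$all_sig_times
  )

  for (mode in c("pRPE", "nRPE", "uRPE")) {
    map <- if (mode == "uRPE") {
      unsigned_rpe_map(rates, trials, mask = mask, thresholds = thresholds)
    } else {
      rpe_correlation_map(rates, trials,
        mode = mode, mask = mask,
        thresholds = thresholds
      )
    }
    det <- detect_encoding(map, thresholds = thresholds)
    rows[[paste0("ns_", mode)]] <- tibble::tibble(
      signal = mode, scope = "nonspecific", dimension = NA_character_,
      flagged = det$encodes, preferred_feature = NA_integer_,
      window_start_s = det$window_start_s, window_len_s = det$window_len_s,
      r_peak = det$r_peak,
      first_run_times = det$first_run_times, all_sig_times = det$all_sig_times
    )
    for (dim in c("color", "location", "motion")) {
      fs <- classify_feature_specific(rates, trials, dim,
        mode = mode,
        mask = mask, thresholds = thresholds
      )
      rows[[paste0("fs_", mode, "_", dim)]] <- tibble::tibble(
        signal = mode, scope = "feature", dimension = dim,
        flagged = fs$evaluable & fs$specific,
        preferred_feature = fs$preferred_feature,
        window_start_s = fs$window_start_s, window_len_s = fs$window_len_s,
        r_peak = fs$r_peak,
        first_run_times = fs$first_run_times, all_sig_times = fs$all_sig_times
      )
    }
  }
  out <- dplyr::bind_cols(base, dplyr::bind_rows(rows))
  attr(out, "inclusion") <- inc
  out
}

#' Finalize label sets across a population
#'
#' Binds per-neuron label tables and computes the exclusive nonspecific flag:
#' for comparison analyses a neuron only counts as a nonspecific RPE neuron
#' for a signal if it was not also identified as feature-specific for that
#' signal (`nonspecific_only` column; feature-specific and
#' nonspecific-only are disjoint populations per signal).
#'
#' @param label_list List of [classify_neuron()] outputs (or one bound
#'   tibble).
#' @return A tibble of all label rows with `nonspecific_only` added.
#' @export
finalize_labels <- function(label_list) {
  labels <- if (is.data.frame(label_list)) {
    label_list
  } else {
    dplyr::bind_rows(label_list)
  }
  if (nrow(labels) == 0) {
    labels$nonspecific_only <- logical(0)
    return(labels)
  }
  fs <- labels |>
    dplyr::filter(.data$scope == "feature", .data$flagged) |>
    dplyr::distinct(.data$neuron, .data$signal) |>
    dplyr::mutate(has_fs = TRUE)
  labels |>
    dplyr::left_join(fs, by = c("neuron", "signal")) |>
    dplyr::mutate(
      nonspecific_only = .data$scope == "nonspecific" & .data$flagged &
        !dplyr::coalesce(.data$has_fs, FALSE)
    ) |>
    dplyr::select(-"has_fs")
}

#' Classify a whole population
#'
#' @param recordings List of `neuron_recording` objects.
#' @param trials,blocks,cfg,thresholds See [classify_neuron()].
#' @return A list: `labels` (finalized label tibble over included neurons)
#'   and `inclusion` (tibble with one row per neuron: `neuron`, `area`,
#'   `included`, `reasons`, `feedback_rate_hz`).
#' @export
classify_population <- function(recordings, trials, blocks,
                                cfg = binning_config(),
                                thresholds = encoding_thresholds()) {
  res <- lapply(recordings, classify_neuron, trials, blocks, cfg, thresholds)
  inclusion <- dplyr::bind_rows(lapply(seq_along(res), function(i) {
    inc <- attr(res[[i]], "inclusion")
    tibble::tibble(
      neuron = recordings[[i]]$id %||% i,
      area = recordings[[i]]$area %||% NA_character_,
      included = inc$include,
      reasons = paste(inc$reasons, collapse = ";"),
      feedback_rate_hz = inc$feedback_rate_hz
    )
  }))
  list(labels = finalize_labels(res), inclusion = inclusion)
}
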