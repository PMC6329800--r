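#' Read and write the pipeline's tabular formats
#'
#' All artifacts are plain delimited text (tab-separated, header row).
#' Trial tables use the columns `session, block, trial, color, location,
#' motion, rewarded, rewarded_color, t_stim_on, t_color_on, t_motion_on,
#' t_dim, t_outcome` (times in seconds from trial start, 0-based trial index
#' within block, features coded 1/2); model columns appended by
#' [rpe_trace()] are preserved. Spike tables use `neuron, trial,
#' alignment_event, spike_time_s` with `trial` the row index into the trial
#' table. Waveform tables are one row per neuron (`neuron`, then one column
#' per sample).
#'
#' @param trials,spikes,waveforms,labels Objects to write.
#' @param path File path.
#' @name featrpe_io
NULL

trial_columns <- c(
  "session", "block", "trial", "color", "location", "motion", "rewarded",
  "rewarded_color", "t_stim_on", "t_color_on", "t_motion_on", "t_dim",
  "t_outcome"
)

#' @rdname featrpe_io
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss)) {
    stop("Trial table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname featrpe_io
#' @export
read_trials <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname featrpe_io
#' @param recordings List of `neuron_recording` objects (for
#'   `write_spikes`/`write_waveforms`).
#' @export
write_spikes <- function(recordings, path) {
  tbl <- dplyr::bind_rows(lapply(recordings, function(r) {
    tibble::tibble(
      neuron = r$id, trial = r$spikes$trial,
      alignment_event = "trial_start", spike_time_s = r$spikes$t
    )
  }))
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname featrpe_io
#' @export
read_spikes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname featrpe_io
#' @export
write_waveforms <- function(recordings, path) {
  tbl <- dplyr::bind_rows(lapply(recordings, function(r) {
    w <- as.numeric(r$waveform)
    out <- tibble::as_tibble(setNames(
      as.list(w),
      sprintf("s%02d", seq_along(w))
    ))
    dplyr::mutate(out, neuron = r$id, .before = 1)
  }))
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname featrpe_io
#' @export
read_waveforms <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname featrpe_io
#' @export
write_labels <- function(labels, path) {
  flat <- labels[, setdiff(
    names(labels),
    c("first_run_times", "all_sig_times")
  )]
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname featrpe_io
#' @param fit An `rl_fit` (for `write_model_fit`).
#' @export
write_model_fit <- function(fit, path) {
  obj <- list(
    variant = fit$spec$variant,
    parameters = as.list(fit$spec$params),
    v0 = fit$spec$v0,
    k = fit$spec$k,
    nll = fit$nll,
    aic = fit$aic,
    n_trials = fit$n_trials,
    seed = fit$seed,
    starts = fit$starts,
    cv_mean_test_ll = if (is.null(fit$cv)) NULL else attr(fit$cv, "mean_test_ll")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname featrpe_io
#' @param config A [task_config()] (for `write_task_config`).
#' @export
write_task_config <- function(config, path) {
  stopifnot(inherits(config, "task_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}

#' @rdname featrpe_io
#' @export
read_task_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  task_config(
    n_blocks = obj$n_blocks,
    block_len_min = obj$block_len_min,
    block_len_max = obj$block_len_max,
    criterion_rate = obj$criterion_rate,
    criterion_window = obj$criterion_window,
    timing = obj$timing
  )
}

#' Validate pipeline input files
#'
#' Schema and integrity diagnostics for trial / spike / waveform tables:
#' required columns, strictly increasing event times, the deterministic
#' reward rule (`rewarded == (color == rewarded_color)`), and referential
#' integrity of spike rows (every referenced trial row exists).
#'
#' @param trials_path,spikes_path,waveforms_path File paths (`NULL` skips).
#' @return A tibble of diagnostics (`file`, `check`, `ok`, `detail`) with
#'   attribute `ok` (all checks passed).
#' @export
validate_inputs <- function(trials_path = NULL, spikes_path = NULL,
                            waveforms_path = NULL) {
  diags <- list()
  add <- function(file, check, ok, detail = "") {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      file = file, check = check, ok = ok, detail = detail
    )
  }
  trials <- NULL
  if (!is.null(trials_path)) {
    trials <- read_trials(trials_path)
    miss <- setdiff(trial_columns, names(trials))
    add(
      trials_path, "columns", length(miss) == 0,
      paste(miss, collapse = ",")
    )
    if (length(miss) == 0) {
      tm <- as.matrix(trials[, c("t_stim_on", "t_dim", "t_outcome")])
      mono <- all(tm[, 1] < tm[, 2] & tm[, 2] < tm[, 3]) &&
        all(trials$t_stim_on < pmin(trials$t_color_on, trials$t_motion_on)) &&
        all(pmax(trials$t_color_on, trials$t_motion_on) < trials$t_dim)
      bad_rows <- which(!(tm[, 1] < tm[, 2] & tm[, 2] < tm[, 3]))
      add(
        trials_path, "event_times_increasing", mono,
        if (mono) "" else paste("rows", paste(head(bad_rows, 5), collapse = ","))
      )
      det <- all(trials$rewarded == as.integer(trials$color == trials$rewarded_color))
      add(trials_path, "deterministic_reward", det)
    }
  }
  if (!is.null(spikes_path)) {
    spikes <- read_spikes(spikes_path)
    need <- c("neuron", "trial", "alignment_event", "spike_time_s")
    miss <- setdiff(need, names(spikes))
    add(spikes_path, "columns", length(miss) == 0, paste(miss, collapse = ","))
    if (length(miss) == 0 && !is.null(trials)) {
      orphan <- which(spikes$trial < 1 | spikes$trial > nrow(trials))
      add(
        spikes_path, "trial_reference", length(orphan) == 0,
        if (length(orphan)) paste("rows", paste(head(orphan, 5), collapse = ",")) else ""
      )
    }
    if (length(miss) == 0) {
      by_nt <- split(spikes$spike_time_s, paste(spikes$neuron, spikes$trial))
      ok_sorted <- all(vapply(by_nt, function(x) !is.unsorted(x), logical(1)))
      add(spikes_path, "spike_times_sorted", ok_sorted)
    }
  }
  if (!is.null(waveforms_path)) {
    wf <- read_waveforms(waveforms_path)
    add(
      waveforms_path, "columns", "neuron" %in% names(wf) && ncol(wf) > 2,
      ""
    )
  }
  out <- dplyr::bind_rows(diags)
  attr(out, "ok") <- all(out$ok)
  out
}
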