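#' Simulate one session of the reversal-learning task
#'
#' Generates `config$n_blocks` blocks of the deterministic color-reward task.
#' Within each block one color is rewarded; reward is delivered iff the
#' chosen stimulus carries that color. A block ends when the running accuracy
#' over the last `criterion_window` trials reaches `criterion_rate` (first
#' checked at trial `block_len_min`) or at `block_len_max` trials, and the
#' rewarded color then reverses unannounced. Location and motion features are
#' pseudo-randomly paired with the colors on every trial. Event times per
#' trial (stimulus onset, color onset, motion onset, dimming, outcome) are
#' drawn from the configured ranges, with color/motion onset order
#' randomized.
#'
#' @param config A [task_config()].
#' @param agent An agent (see [agents]).
#' @param seed Integer seed; the same seed, config and agent reproduce the
#'   session exactly.
#' @param session_id Session label stored in the trial table.
#' @return A list of class `session_behavior` with elements `trials` (tibble,
#'   one row per trial: `session`, `block`, `trial` (0-based within block),
#'   `color`, `location`, `motion` (chosen feature values, 1/2), `rewarded`,
#'   `rewarded_color`, and event times `t_stim_on`, `t_color_on`,
#'   `t_motion_on`, `t_dim`, `t_outcome` in seconds from trial start),
#'   `blocks` (per-block rewarded color, length, learned flag and learning
#'   trial) and `config`.
#' @examples
#' sess <- generate_session(task_config(n_blocks = 3), agent_color_oracle(), seed = 42)
#' sess$blocks
#' @export
generate_session <- function(config, agent, seed, session_id = 1L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(as.integer(seed))
  agent$reset()

  rows <- vector("list", config$n_blocks)
  rewarded_color <- sample(1:2, 1) # first block's rewarded color
  for (b in seq_len(config$n_blocks)) {
    outcomes <- integer(0)
    block_rows <- list()
    t <- 0L
    repeat {
      t <- t + 1L
      # stimulus 1 carries color 1; locations and motions pseudo-random
      loc1 <- sample(1:2, 1)
      mot1 <- sample(1:2, 1)
      stimuli <- list(
        c(1L, loc1, mot1),
        c(2L, 3L - loc1, 3L - mot1)
      )
      pick <- agent$choose(stimuli, rewarded_color)
      chosen <- stimuli[[pick]]
      r <- as.integer(chosen[1] == rewarded_color)
      agent$learn(chosen, r)
      outcomes <- c(outcomes, r)
      block_rows[[t]] <- c(chosen, r)
      done <- (t >= config$block_len_min &&
        mean(tail(outcomes, config$criterion_window)) >= config$criterion_rate) ||
        t >= config$block_len_max
      if (done) break
    }
    m <- do.call(rbind, block_rows)
    rows[[b]] <- tibble::tibble(
      session = as.integer(session_id),
      block = b,
      trial = seq_len(nrow(m)) - 1L,
      color = m[, 1], location = m[, 2], motion = m[, 3],
      rewarded = m[, 4],
      rewarded_color = rewarded_color
    )
    rewarded_color <- 3L - rewarded_color # reversal
  }
  trials <- dplyr::bind_rows(rows)
  trials <- dplyr::bind_cols(trials, draw_event_times(nrow(trials), config$timing))

  out <- structure(
    list(trials = trials, blocks = NULL, config = config),
    class = "session_behavior"
  )
  out$blocks <- annotate_blocks(out)
  out
}

# Event times in seconds from trial start; color/motion onset order random.
draw_event_times <- function(n, timing) {
  t_stim <- runif(n, timing$fix[1], timing$fix[2])
  first <- t_stim + timing$first_feature
  second <- first + runif(n, timing$second_feature[1], timing$second_feature[2])
  color_first <- runif(n) < 0.5
  t_color <- ifelse(color_first, first, second)
  t_motion <- ifelse(color_first, second, first)
  t_dim <- second + runif(n, timing$dim[1], timing$dim[2])
  tibble::tibble(
    t_stim_on = t_stim, t_color_on = t_color, t_motion_on = t_motion,
    t_dim = t_dim, t_outcome = t_dim + timing$outcome
  )
}

# Per-block summary incl. ideal-observer learning trial.
annotate_blocks <- function(session, chance = 0.5) {
  trials <- session$trials
  cfg <- session$config
  trials |>
    dplyr::group_by(.data$session, .data$block) |>
    dplyr::summarise(
      rewarded_color = .data$rewarded_color[1],
      n_trials = dplyr::n(),
      accuracy = mean(.data$rewarded),
      learning_trial = learning_trial(.data$rewarded, chance = chance),
      .groups = "drop"
    ) |>
    dplyr::mutate(learned = !is.na(.data$learning_trial))
}

#' @export
print.session_behavior <- function(x, ...) {
  cat(sprintf(
    "<session_behavior> %d blocks, %d trials, %.0f%% rewarded\n",
    nrow(x$blocks), nrow(x$trials), 100 * mean(x$trials$rewarded)
  ))
  invisible(x)
}

#' Simulate several sessions
#'
#' @inheritParams generate_session
#' @param n_sessions Number of sessions; session `i` uses seed `seed + i - 1`
#'   and a freshly reset agent.
#' @param agent_factory Zero-argument function returning a new agent.
#' @return A list of class `session_set`: `trials` (bound trial table),
#'   `blocks`, `config`.
#' @export
generate_sessions <- function(config, agent_factory, n_sessions, seed) {
  sessions <- lapply(seq_len(n_sessions), function(i) {
    generate_session(config, agent_factory(),
      seed = as.integer(seed) + i - 1L,
      session_id = i
    )
  })
  structure(
    list(
      trials = dplyr::bind_rows(lapply(sessions, `[[`, "trials")),
      blocks = dplyr::bind_rows(lapply(sessions, `[[`, "blocks")),
      config = config
    ),
    class = "session_set"
  )
}

#' Behavioral summary of a session
#'
#' Repeat probabilities conditional on the previous trial being correct
#' (computed within blocks, consecutive trial pairs only), block counts and
#' lengths, and the fraction of blocks learned to the ideal-observer
#' criterion.
#'
#' @param session A `session_behavior` or `session_set`.
#' @return A one-row tibble with `p_repeat_color`, `p_repeat_location`,
#'   `p_repeat_motion` (each `NA` if no previous-correct pairs exist),
#'   `n_blocks`, `mean_block_len`, `median_block_len`, `frac_learned`.
#' @examples
#' sess <- generate_session(task_config(n_blocks = 3), agent_color_wsls(), seed = 1)
#' behavior_summary(sess)
#' @export
behavior_summary <- function(session) {
  trials <- session$trials
  blocks <- session$blocks
  if (nrow(trials) < 2) {
    # repeat probabilities are undefined without a trial pair
    return(tibble::tibble(
      p_repeat_color = NA_real_, p_repeat_location = NA_real_,
      p_repeat_motion = NA_real_, n_blocks = nrow(blocks),
      mean_block_len = NA_real_, median_block_len = NA_real_,
      frac_learned = NA_real_
    ))
  }
  prev_ok <- dplyr::lag(trials$rewarded) == 1 &
    dplyr::lag(trials$block) == trials$block &
    dplyr::lag(trials$session) == trials$session
  prev_ok[is.na(prev_ok)] <- FALSE
  rep_prob <- function(x) {
    if (!any(prev_ok)) {
      return(NA_real_)
    }
    mean((x == dplyr::lag(x))[prev_ok])
  }
  tibble::tibble(
    p_repeat_color = rep_prob(trials$color),
    p_repeat_location = rep_prob(trials$location),
    p_repeat_motion = rep_prob(trials$motion),
    n_blocks = nrow(blocks),
    mean_block_len = mean(blocks$n_trials),
    median_block_len = median(blocks$n_trials),
    frac_learned = mean(blocks$learned)
  )
}
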