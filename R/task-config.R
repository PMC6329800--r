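#' Task configuration for the feature-based reversal-learning task
#'
#' Builds the configuration object describing the deterministic color-reward
#' reversal task: two peripheral stimuli that each carry one feature per
#' dimension (color, location, motion direction), with only color linked to
#' reward. A block keeps one rewarded color for 30 to 100 trials and ends as
#' soon as the running accuracy over the last `criterion_window` trials
#' reaches `criterion_rate` (checked from trial `block_len_min` onward), after
#' which the color-reward association reverses unannounced.
#'
#' @param n_blocks Number of reversal blocks per session.
#' @param block_len_min,block_len_max Minimum / maximum block length (trials).
#' @param criterion_rate Running-accuracy level that triggers a reversal.
#' @param criterion_window Number of trials in the running-accuracy window.
#' @param timing Named list of event-timing ranges in seconds:
#'   `fix` (fixation to stimulus onset), `first_feature` (stimulus onset to
#'   the first feature onset, fixed), `second_feature` (first to second
#'   feature onset), `dim` (second feature onset to dimming), and `outcome`
#'   (dimming to outcome delivery, fixed).
#'
#' @return A list of class `task_config`.
#' @examples
#' cfg <- task_config(n_blocks = 4)
#' cfg$criterion_rate
#' @export
task_config <- function(n_blocks = 9,
                        block_len_min = 30,
                        block_len_max = 100,
                        criterion_rate = 0.90,
                        criterion_window = 12,
                        timing = list(
                          fix = c(0.5, 0.9),
                          first_feature = 0.4,
                          second_feature = c(0.5, 0.9),
                          dim = c(0.4, 1.0),
                          outcome = 0.3
                        )) {
  if (block_len_min > block_len_max) {
    stop("`block_len_min` must not exceed `block_len_max`.", call. = FALSE)
  }
  if (criterion_window > block_len_min) {
    stop("`criterion_window` must not exceed `block_len_min`.", call. = FALSE)
  }
  if (criterion_rate <= 0 || criterion_rate > 1) {
    stop("`criterion_rate` must lie in (0, 1].", call. = FALSE)
  }
  stopifnot(n_blocks >= 1)
  for (nm in c("fix", "second_feature", "dim")) {
    rng <- timing[[nm]]
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 0) {
      stop(sprintf("timing$%s must be a nondecreasing nonnegative range.", nm),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      n_dimensions = 3L,
      features_per_dimension = 2L,
      dimensions = c("color", "location", "motion"),
      reward_relevant_dimension = "color",
      n_blocks = as.integer(n_blocks),
      block_len_min = as.integer(block_len_min),
      block_len_max = as.integer(block_len_max),
      criterion_rate = criterion_rate,
      criterion_window = as.integer(criterion_window),
      timing = timing
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf(
    "  dimensions: %s (reward-relevant: %s)\n",
    paste(x$dimensions, collapse = ", "), x$reward_relevant_dimension
  ))
  cat(sprintf(
    "  blocks/session: %d, block length %d-%d trials\n",
    x$n_blocks, x$block_len_min, x$block_len_max
  ))
  cat(sprintf(
    "  reversal criterion: %.0f%% over last %d trials\n",
    100 * x$criterion_rate, x$criterion_window
  ))
  invisible(x)
}

# Feature labels used throughout: each dimension has two feature values coded
# 1/2; human-readable labels for tables and plots.
feature_labels <- function() {
  list(
    color = c("c1", "c2"),
    location = c("L", "R"),
    motion = c("up", "down")
  )
}
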