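#' Initial model state
#'
#' Feature values start at the unbiased prior `v0` for all six features (two
#' per dimension) and dimension weights start uniform.
#'
#' @param v0 Initial feature value.
#' @return A list with `V` (2 x 3 matrix, feature value x dimension) and `w`
#'   (length-3 dimension weights summing to 1).
#' @export
model_state <- function(v0 = 0.5) {
  list(
    V = matrix(v0, 2, 3, dimnames = list(NULL, c("color", "location", "motion"))),
    w = rep(1 / 3, 3)
  )
}

#' Value of a stimulus under the current model state
#'
#' Linear aggregation of the stimulus's feature values: `V = sum_d w_d *
#' V[f_d, d]`. The F-S variant uses the color value alone; F-NS and F-Dec use
#' fixed uniform weights.
#'
#' @param state A [model_state()].
#' @param stimulus Integer vector of length 3: the stimulus's feature value
#'   (1 or 2) on each of color, location, motion.
#' @param variant Model variant name.
#' @return Scalar stimulus value.
#' @export
stimulus_value <- function(state, stimulus, variant = "F-DW-Dec") {
  if (length(stimulus) != 3 || anyNA(stimulus) ||
    !all(stimulus %in% c(1L, 2L))) {
    stop("`stimulus` must give a feature value (1 or 2) for all 3 dimensions.",
      call. = FALSE
    )
  }
  v <- state$V[cbind(stimulus, 1:3)]
  switch(variant,
    "F-S" = v[1],
    "F-NS" = ,
    "F-Dec" = mean(v),
    sum(state$w * v)
  )
}

#' Softmax choice probabilities over a stimulus pair
#'
#' `P(i) = exp(beta * V_i) / sum_j exp(beta * V_j)`; `beta = 0` gives random
#' choice.
#'
#' @inheritParams stimulus_value
#' @param stimuli List of two stimulus feature triples.
#' @param beta Selection noise (inverse temperature).
#' @return Numeric vector of two probabilities summing to 1.
#' @export
choice_probabilities <- function(state, stimuli, beta, variant = "F-DW-Dec") {
  stopifnot(beta >= 0, length(stimuli) == 2)
  v <- vapply(stimuli, stimulus_value, numeric(1),
    state = state, variant = variant
  )
  z <- beta * (v - max(v)) # stabilized softmax
  p <- exp(z) / sum(exp(z))
  names(p) <- NULL
  p
}

#' Update dimension weights from feature-value predictiveness
#'
#' Each dimension's predictiveness signal is the absolute difference between
#' its two feature values, `s_d = |V[1, d] - V[2, d]|`. Weights move toward
#' the normalized shares `s_d / sum(s)` at rate `phi` (toward uniform if all
#' `s_d = 0`) and are renormalized to sum to 1.
#'
#' @inheritParams stimulus_value
#' @param phi Dimension-weighting rate in `[0, 1]`.
#' @return Updated model state.
#' @export
update_dimension_weights <- function(state, phi) {
  stopifnot(phi >= 0, phi <= 1)
  s <- abs(state$V[1, ] - state$V[2, ])
  target <- if (sum(s) > 0) s / sum(s) else rep(1 / 3, 3)
  w <- (1 - phi) * state$w + phi * target
  state$w <- unname(w / sum(w))
  state
}

#' One reinforcement-learning update
#'
#' Computes the reward prediction error `RPE = R - V(chosen)` and applies the
#' variant's update: chosen features move toward the outcome at rate
#' `eta * g_d` where the gate `g_d` is 1 (F-NS, F-Dec, and color for F-S) or
#' the dimension weight `w_d` (F-DW, F-DW-Dec); for decay variants the
#' nonchosen stimulus's features decay as `V <- omega * V + (1 - omega) * v0`;
#' for weighted variants the dimension weights are then updated via
#' [update_dimension_weights()].
#'
#' @inheritParams stimulus_value
#' @param chosen Feature triple of the chosen stimulus.
#' @param reward Outcome, 0 or 1.
#' @param spec A [model_spec()].
#' @return A list with `state` (updated) and `rpe`.
#' @export
rl_update <- function(state, chosen, reward, spec) {
  if (length(reward) != 1 || !reward %in% c(0, 1)) {
    stop("`reward` must be 0 or 1.", call. = FALSE)
  }
  p <- full_params(spec)
  v <- stimulus_value(state, chosen, spec$variant)
  rpe <- reward - v

  gate <- switch(spec$variant,
    "F-DW" = ,
    "F-DW-Dec" = state$w,
    rep(1, 3)
  )
  dims <- if (spec$variant == "F-S") 1L else 1:3
  idx <- cbind(chosen[dims], dims)
  state$V[idx] <- state$V[idx] + p["eta"] * gate[dims] * rpe

  if (spec$variant %in% c("F-Dec", "F-DW-Dec")) {
    other <- cbind(3L - chosen, 1:3) # the nonchosen stimulus's features
    state$V[other] <- p["omega"] * state$V[other] + (1 - p["omega"]) * spec$v0
  }
  if (spec$variant %in% c("F-DW", "F-DW-Dec")) {
    state <- update_dimension_weights(state, p["phi"])
  }
  list(state = state, rpe = unname(rpe))
}

# Pure-R forward pass over a trial table: evolves the model state trial by
# trial (reset at session boundaries, never at block boundaries) and returns
# per-trial V_chosen, rpe and the probability of the observed choice. The
# compiled rl_forward_cpp() is the fast path; this version is its oracle.
rl_forward_r <- function(spec, trials) {
  n <- nrow(trials)
  chosen <- as.matrix(trials[, c("color", "location", "motion")])
  v_chosen <- rpe <- p_choice <- numeric(n)
  state <- model_state(spec$v0)
  beta <- full_params(spec)[["beta"]]
  prev_session <- NULL
  for (t in seq_len(n)) {
    if (!identical(trials$session[t], prev_session)) {
      state <- model_state(spec$v0)
      prev_session <- trials$session[t]
    }
    ch <- chosen[t, ]
    other <- 3L - ch
    p <- choice_probabilities(state, list(ch, other), beta, spec$variant)
    v_chosen[t] <- stimulus_value(state, ch, spec$variant)
    p_choice[t] <- p[1]
    up <- rl_update(state, ch, trials$rewarded[t], spec)
    state <- up$state
    rpe[t] <- up$rpe
  }
  tibble::tibble(v_chosen = v_chosen, rpe = rpe, p_choice = p_choice)
}
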