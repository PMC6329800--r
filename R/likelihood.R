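#' Per-trial model trace: value, RPE, choice probability
#'
#' Runs the model forward over a trial table (state reset at session starts
#' only — reversals are uncued to the model) and joins the per-trial chosen
#' stimulus value `v_chosen`, reward prediction error `rpe = rewarded -
#' v_chosen`, and the softmax probability of the observed choice `p_choice`
#' onto the table.
#'
#' @param spec A [model_spec()].
#' @param trials A trial table as produced by [generate_session()] (columns
#'   `session`, `color`, `location`, `motion`, `rewarded` at minimum).
#' @return The trial table with columns `v_chosen`, `rpe`, `p_choice` and
#'   `model_variant` appended.
#' @examples
#' sess <- generate_session(task_config(n_blocks = 2), agent_random(), seed = 1)
#' head(rpe_trace(model_spec("F-NS", eta = 0.3, beta = 2), sess$trials))
#' @export
rpe_trace <- function(spec, trials) {
  check_trials(trials)
  fwd <- rl_forward(spec, trials)
  trials$v_chosen <- fwd$v_chosen
  trials$rpe <- fwd$rpe
  trials$p_choice <- fwd$p_choice
  trials$model_variant <- spec$variant
  trials
}

# Compiled forward pass with the R reference available for cross-checks.
rl_forward <- function(spec, trials, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "r") {
    return(rl_forward_r(spec, trials))
  }
  chosen <- as.matrix(trials[, c("color", "location", "motion")])
  storage.mode(chosen) <- "integer"
  out <- rl_forward_cpp(
    chosen, as.numeric(trials$rewarded), new_session_flags(trials$session),
    full_params(spec), variant_code(spec$variant), spec$v0
  )
  tibble::as_tibble(out)
}

new_session_flags <- function(session) {
  n <- length(session)
  if (n == 0) {
    return(logical(0))
  }
  c(TRUE, session[-1] != session[-n])
}

check_trials <- function(trials) {
  need <- c("session", "color", "location", "motion", "rewarded")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("Trial table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  feats <- as.matrix(trials[, c("color", "location", "motion")])
  if (nrow(trials) && (anyNA(feats) || !all(feats %in% c(1L, 2L)))) {
    stop("Chosen features must be coded 1 or 2.", call. = FALSE)
  }
  if (nrow(trials) && !all(trials$rewarded %in% c(0, 1))) {
    stop("`rewarded` must be 0 or 1.", call. = FALSE)
  }
  invisible(trials)
}

#' Negative log likelihood of observed choices under a model
#'
#' `NLL = -sum_t log P(chosen_t)` with the state evolving trial by trial.
#' Probabilities are floored at `p_floor` (default 1e-9) before taking logs;
#' a warning notes when the floor was hit.
#'
#' @inheritParams rpe_trace
#' @param p_floor Probability floor applied inside the log.
#' @return Scalar negative log likelihood.
#' @examples
#' sess <- generate_session(task_config(n_blocks = 2), agent_random(), seed = 1)
#' negative_log_likelihood(model_spec("F-NS", eta = 0.3, beta = 0), sess$trials)
#' nrow(sess$trials) * log(2) # beta = 0 reference
#' @export
negative_log_likelihood <- function(spec, trials, p_floor = 1e-9) {
  check_trials(trials)
  p <- rl_forward(spec, trials)$p_choice
  if (any(p < p_floor)) {
    warning(sprintf(
      "%d choice probabilities floored at %g in the likelihood.",
      sum(p < p_floor), p_floor
    ), call. = FALSE)
  }
  -sum(log(pmax(p, p_floor)))
}

# NLL as a function of a raw parameter vector for the optimizer (no input
# revalidation, no warnings: called thousands of times).
nll_objective <- function(theta, free, trials_prep, variant, v0,
                          p_floor = 1e-9) {
  params <- c(eta = NA_real_, beta = NA_real_, phi = 0, omega = 1)
  params[free] <- theta
  out <- rl_forward_cpp(
    trials_prep$chosen, trials_prep$reward, trials_prep$new_session,
    params, variant_code(variant), v0
  )
  -sum(log(pmax(out$p_choice, p_floor)))
}

prep_trials <- function(trials) {
  chosen <- as.matrix(trials[, c("color", "location", "motion")])
  storage.mode(chosen) <- "integer"
  list(
    chosen = chosen,
    reward = as.numeric(trials$rewarded),
    new_session = new_session_flags(trials$session)
  )
}
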