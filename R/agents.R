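#' Choice agents for task simulation
#'
#' An agent is a list of three closures that [generate_session()] calls:
#' `reset()` at session start, `choose(stimuli, rewarded_color)` returning 1
#' or 2 for the index of the chosen stimulus, and `learn(chosen, reward)`
#' called after the outcome. `stimuli` is a list of two feature triples
#' (color, location, motion coded 1/2). `rewarded_color` is supplied so that
#' oracle agents used in tests can behave perfectly; behaving agents ignore
#' it.
#'
#' * `agent_rl(spec)` chooses by the model's softmax rule and learns by its
#'   update rule — the generative agent for self-consistent model recovery.
#' * `agent_random()` chooses uniformly.
#' * `agent_color_oracle()` always picks the stimulus with the rewarded
#'   color.
#' * `agent_color_wsls()` repeats its color choice after reward and switches
#'   after nonreward (win-stay/lose-shift on color).
#'
#' @param spec A [model_spec()] (for `agent_rl`).
#' @return An agent list with elements `reset`, `choose`, `learn` and `name`.
#' @examples
#' ag <- agent_rl(model_spec("F-DW-Dec", eta = 0.22, beta = 3.55, phi = 0.68, omega = 0.92))
#' ag$reset()
#' @name agents
NULL

#' @rdname agents
#' @export
agent_rl <- function(spec) {
  state <- model_state(spec$v0)
  beta <- full_params(spec)[["beta"]]
  list(
    name = paste0("rl:", spec$variant),
    reset = function() state <<- model_state(spec$v0),
    choose = function(stimuli, rewarded_color) {
      p <- choice_probabilities(state, stimuli, beta, spec$variant)
      if (runif(1) < p[1]) 1L else 2L
    },
    learn = function(chosen, reward) {
      state <<- rl_update(state, chosen, reward, spec)$state
    }
  )
}

#' @rdname agents
#' @export
agent_random <- function() {
  list(
    name = "random",
    reset = function() invisible(NULL),
    choose = function(stimuli, rewarded_color) sample(1:2, 1),
    learn = function(chosen, reward) invisible(NULL)
  )
}

#' @rdname agents
#' @export
agent_color_oracle <- function() {
  list(
    name = "oracle",
    reset = function() invisible(NULL),
    choose = function(stimuli, rewarded_color) {
      if (stimuli[[1]][1] == rewarded_color) 1L else 2L
    },
    learn = function(chosen, reward) invisible(NULL)
  )
}

#' @rdname agents
#' @export
agent_color_wsls <- function() {
  target <- 1L
  list(
    name = "wsls",
    reset = function() target <<- 1L,
    choose = function(stimuli, rewarded_color) {
      if (stimuli[[1]][1] == target) 1L else 2L
    },
    learn = function(chosen, reward) {
      target <<- if (reward == 1) chosen[1] else 3L - chosen[1]
    }
  )
}
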