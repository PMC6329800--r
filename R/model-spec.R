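#' Specify a reinforcement-learning model variant
#'
#' The model family contains five variants that differ in how reward
#' prediction errors (RPEs) update feature values of the chosen stimulus:
#'
#' * `"F-NS"` — feature-nonselective: the RPE updates all three chosen
#'   features equally; dimension weights fixed at 1/3.
#' * `"F-S"` — feature-selective: only the chosen color value is learned and
#'   only color determines stimulus value (a fixed attentional set).
#' * `"F-DW"` — dimension-weighted: as F-NS, but a learned weight per
#'   dimension both gates the update and aggregates feature values into
#'   stimulus value; weights track each dimension's predictiveness at rate
#'   `phi`.
#' * `"F-Dec"` — as F-NS plus decay of the nonchosen stimulus's feature
#'   values toward the prior `v0` at rate `omega`.
#' * `"F-DW-Dec"` — combines dimension weighting and decay (4 free
#'   parameters).
#'
#' Parameter naming follows the convention of calling the dimension-weighting
#' rate `phi`; the same quantity is sometimes labelled alpha in figure
#' legends of the attention-weighted RL literature.
#'
#' @param variant One of `"F-NS"`, `"F-S"`, `"F-DW"`, `"F-Dec"`, `"F-DW-Dec"`.
#' @param eta Learning rate in `[0, 1]`.
#' @param beta Softmax selection noise (inverse temperature), `>= 0`.
#' @param phi Dimension-weighting rate in `[0, 1]` (F-DW, F-DW-Dec only).
#' @param omega Decay rate for nonchosen-stimulus feature values in `[0, 1]`
#'   (F-Dec, F-DW-Dec only); `omega = 1` means no decay.
#' @param v0 Initial (and decay-target) feature value.
#'
#' @return A list of class `model_spec` with elements `variant`, `params`
#'   (named numeric vector of the free parameters), `v0`, `k` (number of free
#'   parameters) and `bounds`.
#' @examples
#' model_spec("F-DW-Dec", eta = 0.22, beta = 3.55, phi = 0.68, omega = 0.92)
#' @export
model_spec <- function(variant = c("F-NS", "F-S", "F-DW", "F-Dec", "F-DW-Dec"),
                       eta = 0.3, beta = 3, phi = 0.5, omega = 0.9,
                       v0 = 0.5) {
  variant <- match.arg(variant)
  free <- free_params(variant)
  params <- c(eta = eta, beta = beta, phi = phi, omega = omega)[free]
  bounds <- param_bounds()[free, , drop = FALSE]
  bad <- params < bounds[, "lower"] | params > bounds[, "upper"]
  if (any(bad)) {
    stop(
      "Parameter(s) out of bounds: ",
      paste(names(params)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      variant = variant, params = params, v0 = v0,
      k = length(free), bounds = bounds
    ),
    class = "model_spec"
  )
}

free_params <- function(variant) {
  switch(variant,
    "F-NS" = c("eta", "beta"),
    "F-S" = c("eta", "beta"),
    "F-DW" = c("eta", "beta", "phi"),
    "F-Dec" = c("eta", "beta", "omega"),
    "F-DW-Dec" = c("eta", "beta", "phi", "omega")
  )
}

param_bounds <- function() {
  matrix(
    c(
      0, 1, # eta
      0, 20, # beta
      0, 1, # phi
      0, 1 # omega
    ),
    ncol = 2, byrow = TRUE,
    dimnames = list(c("eta", "beta", "phi", "omega"), c("lower", "upper"))
  )
}

# Full parameter vector (eta, beta, phi, omega) with fixed values for the
# parameters a variant does not use: phi irrelevant (weights stay uniform
# because the update is skipped), omega = 1 (no decay).
full_params <- function(spec) {
  p <- c(eta = NA_real_, beta = NA_real_, phi = 0, omega = 1)
  p[names(spec$params)] <- spec$params
  p
}

variant_code <- function(variant) {
  match(variant, c("F-NS", "F-S", "F-DW", "F-Dec", "F-DW-Dec"))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %s (%d free parameters)\n  %s\n", x$variant, x$k,
    paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", ")
  ))
  invisible(x)
}
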