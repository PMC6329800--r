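#' Fit an RL model variant by maximum likelihood
#'
#' Multi-start maximum-likelihood estimation: every start runs a simplex
#' (Nelder-Mead) search to initialize a bounded quasi-Newton (L-BFGS-B)
#' refinement, and the best refined start wins. Starts combine a fixed
#' coarse grid over the free parameters (two levels per parameter, so the
#' basin structure of the likelihood is covered systematically) with
#' `n_random` additional uniform draws from `seed`; refitting with the same
#' seed reproduces the result exactly. Trials can be restricted with `mask`
#' (the state still evolves over all trials; only masked trials enter the
#' likelihood), which is how block-wise cross-validation scores held-out
#' blocks without breaking the state sequence.
#'
#' @param variant Model variant name (see [model_spec()]).
#' @param trials Trial table (see [generate_session()]).
#' @param seed Integer seed for the random start draws.
#' @param n_random Number of random starts added to the fixed grid.
#' @param mask Optional logical vector over trials; `TRUE` trials enter the
#'   likelihood.
#' @param v0 Initial feature value.
#' @param simplex_iter Simplex iterations used to warm-start each refinement.
#' @return An object of class `rl_fit`: the fitted [model_spec()], `nll`,
#'   `aic` (`2k + 2 NLL`), `n_trials`, a `starts` tibble recording every
#'   start and its converged value, and `trace` (per-trial `v_chosen`, `rpe`,
#'   `p_choice` under the fitted parameters, over all trials).
#' @examples
#' \donttest{
#' sess <- generate_sessions(
#'   task_config(n_blocks = 4),
#'   function() agent_rl(model_spec("F-NS", eta = 0.4, beta = 4)),
#'   n_sessions = 2, seed = 7
#' )
#' fit <- fit_rl("F-NS", sess$trials, seed = 1)
#' generics::tidy(fit)
#' }
#' @export
fit_rl <- function(variant, trials, seed, n_random = 2, mask = NULL,
                   v0 = 0.5, simplex_iter = 300) {
  check_trials(trials)
  free <- free_params(variant)
  bounds <- param_bounds()[free, , drop = FALSE]
  prep <- prep_trials(trials)
  if (is.null(mask)) mask <- rep(TRUE, nrow(trials))
  stopifnot(length(mask) == nrow(trials))

  obj <- function(theta) {
    theta <- pmin(pmax(theta, bounds[, "lower"]), bounds[, "upper"])
    nll_objective_masked(theta, free, prep, variant, v0, mask)
  }

  grid_levels <- list(
    eta = c(0.1, 0.4), beta = c(2, 6), phi = c(0.25, 0.75),
    omega = c(0.7, 0.95)
  )
  starts <- as.matrix(expand.grid(grid_levels[free]))
  if (n_random > 0) {
    set.seed(as.integer(seed))
    rand <- matrix(
      runif(n_random * length(free), bounds[, "lower"], bounds[, "upper"]),
      nrow = n_random, byrow = TRUE, dimnames = list(NULL, free)
    )
    if ("beta" %in% free) rand[, "beta"] <- runif(n_random, 0.5, 8)
    starts <- rbind(starts, rand)
  }
  n_starts <- nrow(starts)

  eps <- 1e-6
  results <- lapply(seq_len(n_starts), function(i) {
    warm <- tryCatch(
      optim(starts[i, ], obj,
        method = "Nelder-Mead",
        control = list(maxit = simplex_iter, reltol = 1e-8)
      ),
      error = function(e) list(par = starts[i, ], value = obj(starts[i, ]))
    )
    par0 <- pmin(pmax(warm$par, bounds[, "lower"] + eps), bounds[, "upper"] - eps)
    fine <- tryCatch(
      optim(par0, obj,
        method = "L-BFGS-B",
        lower = bounds[, "lower"] + eps, upper = bounds[, "upper"] - eps
      ),
      error = function(e) NULL
    )
    if (is.null(fine) || fine$value > warm$value) {
      list(par = warm$par, value = warm$value, converged = !is.null(fine))
    } else {
      list(par = fine$par, value = fine$value, converged = fine$convergence == 0)
    }
  })
  values <- vapply(results, `[[`, numeric(1), "value")
  if (all(!vapply(results, `[[`, logical(1), "converged")) &&
    all(!is.finite(values))) {
    stop("Optimizer failed to converge from every start.", call. = FALSE)
  }
  best <- results[[which.min(values)]]

  # the simplex phase is unconstrained (the objective clamps internally)
  pars <- as.list(pmin(pmax(best$par, bounds[, "lower"]), bounds[, "upper"]))
  names(pars) <- free
  spec <- do.call(model_spec, c(list(variant = variant, v0 = v0), pars))
  nll <- best$value
  starts_tbl <- tibble::tibble(
    start = seq_len(n_starts),
    value = values,
    converged = vapply(results, `[[`, logical(1), "converged")
  )
  structure(
    list(
      spec = spec, nll = nll, aic = 2 * spec$k + 2 * nll,
      n_trials = sum(mask), n_trials_total = nrow(trials),
      data_checksum = trials_checksum(trials),
      starts = starts_tbl, seed = as.integer(seed),
      trace = rl_forward(spec, trials),
      cv = NULL
    ),
    class = "rl_fit"
  )
}

nll_objective_masked <- function(theta, free, prep, variant, v0, mask,
                                 p_floor = 1e-9) {
  params <- c(eta = NA_real_, beta = NA_real_, phi = 0, omega = 1)
  params[free] <- theta
  out <- rl_forward_cpp(
    prep$chosen, prep$reward, prep$new_session,
    params, variant_code(variant), v0
  )
  -sum(log(pmax(out$p_choice[mask], p_floor)))
}

# Order-sensitive checksum used to verify that compared fits saw the same data.
trials_checksum <- function(trials) {
  m <- as.matrix(trials[, c("color", "location", "motion", "rewarded")])
  sum(m * (seq_len(nrow(m)) %% 97 + 1)) + nrow(m) * 1e6
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf(
    "<rl_fit> %s: NLL = %.2f, AIC = %.2f over %d trials\n  %s\n",
    x$spec$variant, x$nll, x$aic, x$n_trials,
    paste(sprintf("%s = %.4g", names(x$spec$params), x$spec$params),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Block-wise cross-validation of an RL model
#'
#' Repeatedly fits on a random `split` fraction of blocks and evaluates the
#' log likelihood of the held-out blocks under the fitted parameters (the
#' model state evolves over the full trial sequence in both phases; only the
#' respective blocks are scored, so no held-out choice enters the training
#' objective).
#'
#' @inheritParams fit_rl
#' @param split Fraction of blocks in the training set.
#' @param reps Number of random splits.
#' @return A tibble with one row per repetition: `rep`, `n_test_trials`,
#'   `test_ll` (log likelihood, higher is better) plus attribute
#'   `mean_test_ll`.
#' @export
cross_validate_rl <- function(variant, trials, seed, split = 0.8, reps = 50,
                              n_random = 0, v0 = 0.5) {
  check_trials(trials)
  blocks <- unique(trials[, c("session", "block")])
  n_blocks <- nrow(blocks)
  if (n_blocks < 5) {
    stop("Need at least 5 blocks for an 80/20 split.", call. = FALSE)
  }
  n_train <- max(1, round(split * n_blocks))
  if (n_train == n_blocks) n_train <- n_blocks - 1
  block_id <- paste(trials$session, trials$block)
  ids <- paste(blocks$session, blocks$block)

  res <- lapply(seq_len(reps), function(r) {
    set.seed(as.integer(seed) + 7919L * r)
    train_ids <- sample(ids, n_train)
    train_mask <- block_id %in% train_ids
    fit <- fit_rl(variant, trials,
      seed = as.integer(seed) + r, n_random = n_random,
      mask = train_mask, v0 = v0
    )
    p <- rl_forward(fit$spec, trials)$p_choice
    test_mask <- !train_mask
    tibble::tibble(
      rep = r,
      n_test_trials = sum(test_mask),
      test_ll = sum(log(pmax(p[test_mask], 1e-9)))
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "mean_test_ll") <- mean(out$test_ll)
  out
}

#' Compare fitted RL models
#'
#' @param fits List of `rl_fit` objects fitted to the same trials, optionally
#'   carrying a `cv` element (a [cross_validate_rl()] result).
#' @return A tibble with `variant`, `k`, `nll`, `aic`, `mean_test_ll`,
#'   `aic_best` and `cv_best` flags, sorted by AIC.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  checksums <- vapply(fits, `[[`, numeric(1), "data_checksum")
  if (length(unique(checksums)) != 1) {
    stop("All fits must be computed on the same trial data.", call. = FALSE)
  }
  tbl <- tibble::tibble(
    variant = vapply(fits, function(f) f$spec$variant, character(1)),
    k = vapply(fits, function(f) f$spec$k, numeric(1)),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    mean_test_ll = vapply(fits, function(f) {
      if (is.null(f$cv)) NA_real_ else attr(f$cv, "mean_test_ll")
    }, numeric(1))
  )
  tbl$aic_best <- tbl$aic == min(tbl$aic)
  tbl$cv_best <- if (all(is.na(tbl$mean_test_ll))) {
    FALSE
  } else {
    !is.na(tbl$mean_test_ll) &
      tbl$mean_test_ll == max(tbl$mean_test_ll, na.rm = TRUE)
  }
  dplyr::arrange(tbl, .data$aic)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_sessions` sessions of behavior from a generating model,
#' refits the same variant by multi-start maximum likelihood, and repeats the
#' whole simulate-and-refit cycle `n_replicates` times. The median of each
#' parameter's estimates across replicates is the standard summary of how
#' well the experimental design identifies the model.
#'
#' @param spec Generating [model_spec()].
#' @param n_sessions Sessions per replicate.
#' @param n_replicates Number of simulate-and-refit replicates.
#' @param seed Integer seed; replicate `r` derives its own simulation and
#'   fitting seeds from it.
#' @param config A [task_config()].
#' @param n_random Extra random optimizer starts (see [fit_rl()]).
#' @return A tibble with one row per replicate: `replicate`, `n_trials`,
#'   `nll`, and one column per free parameter; attribute `medians` holds the
#'   named vector of median estimates.
#' @export
recover_parameters <- function(spec, n_sessions = 50, n_replicates = 10,
                               seed = 1, config = task_config(),
                               n_random = 0) {
  seed <- as.integer(seed)
  rows <- lapply(seq_len(n_replicates), function(r) {
    sim_seed <- (seed * 10007L + r * 997L) %% 2147483647L
    ss <- generate_sessions(config, function() agent_rl(spec),
      n_sessions = n_sessions, seed = sim_seed
    )
    fit <- fit_rl(spec$variant, ss$trials,
      seed = (sim_seed + 31L) %% 2147483647L, n_random = n_random,
      v0 = spec$v0
    )
    out <- tibble::tibble(
      replicate = r, n_trials = nrow(ss$trials), nll = fit$nll
    )
    dplyr::bind_cols(out, tibble::as_tibble(as.list(fit$spec$params)))
  })
  out <- dplyr::bind_rows(rows)
  pars <- names(spec$params)
  attr(out, "medians") <- vapply(out[pars], median, numeric(1))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted RL model
#'
#' @param x An `rl_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `lower`, `upper` (the optimization bounds).
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$spec$params),
    estimate = unname(x$spec$params),
    lower = x$spec$bounds[, "lower"],
    upper = x$spec$bounds[, "upper"]
  )
}

#' Glance at a fitted RL model
#'
#' @inheritParams tidy.rl_fit
#' @return One-row tibble: `variant`, `k`, `nll`, `aic`, `n_trials`,
#'   `mean_test_ll`.
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant, k = x$spec$k, nll = x$nll, aic = x$aic,
    n_trials = x$n_trials,
    mean_test_ll = if (is.null(x$cv)) NA_real_ else attr(x$cv, "mean_test_ll")
  )
}
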