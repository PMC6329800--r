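test_that("stimulus value aggregates feature values linearly", {
  st <- model_state(0.5)
  expect_equal(stimulus_value(st, c(1L, 1L, 1L)), 0.5) # convexity at equal V

  st$w <- c(1, 0, 0)
  st$V[1, "color"] <- 0.8
  expect_equal(stimulus_value(st, c(1L, 2L, 2L), "F-DW"), 0.8)

  st2 <- model_state()
  st2$w <- c(0.5, 0.25, 0.25)
  st2$V[cbind(c(1, 1, 1), 1:3)] <- c(0.8, 0.4, 0.4)
  expect_equal(stimulus_value(st2, c(1L, 1L, 1L), "F-DW"), 0.6)

  expect_error(stimulus_value(st, c(1L, 3L, 1L)), "feature value")
})

test_that("softmax choice probabilities behave as specified", {
  st <- model_state()
  stimuli <- list(c(1L, 1L, 1L), c(2L, 2L, 2L))
  expect_equal(choice_probabilities(st, stimuli, beta = 0), c(0.5, 0.5))
  expect_equal(choice_probabilities(st, stimuli, beta = 7), c(0.5, 0.5))

  st$V[cbind(c(1, 2), c(1, 1))] <- c(0.75, 0.25)
  st$w <- c(1, 0, 0)
  p <- choice_probabilities(st, stimuli, beta = 3.55, "F-DW")
  expect_equal(p[1], 1 / (1 + exp(-3.55 * 0.5)), tolerance = 1e-12)
  expect_equal(sum(p), 1)
})

test_that("the RL update implements RPE = R - V and the variant rules", {
  spec <- model_spec("F-NS", eta = 0.5, beta = 2)
  st <- model_state(0.5)
  st$V[cbind(c(1, 1, 1), 1:3)] <- 0.75
  up <- rl_update(st, c(1L, 1L, 1L), reward = 1, spec)
  expect_equal(up$rpe, 0.25)

  # eta = 0 and omega = 1 leave the state unchanged but still report the RPE
  spec0 <- model_spec("F-DW-Dec", eta = 0, beta = 2, phi = 0, omega = 1)
  st0 <- model_state()
  up0 <- rl_update(st0, c(1L, 2L, 1L), reward = 0, spec0)
  expect_equal(up0$state$V, st0$V)
  expect_equal(up0$rpe, -0.5)

  # hand iteration: F-NS from the prior, rewarded
  up1 <- rl_update(model_state(0.5), c(1L, 1L, 1L), 1, spec)
  expect_equal(up1$rpe, 0.5)
  expect_equal(unname(up1$state$V[cbind(c(1, 1, 1), 1:3)]), rep(0.75, 3))

  expect_error(rl_update(model_state(), c(1L, 1L, 1L), 2, spec), "0 or 1")
})

test_that("dimension-weight update tracks predictiveness shares", {
  st <- model_state()
  st$V[1, ] <- c(0.9, 0.7, 0.5)
  st$V[2, ] <- c(0.5, 0.3, 0.1) # equal |differences| -> uniform fixed point
  st2 <- update_dimension_weights(st, phi = 0.8)
  expect_equal(st2$w, rep(1 / 3, 3))

  st$V[1, ] <- c(0.9, 0.5, 0.5)
  st$V[2, ] <- c(0.1, 0.5, 0.5) # only color predictive
  st3 <- update_dimension_weights(st, phi = 1)
  expect_equal(st3$w, c(1, 0, 0))

  st$V[1, ] <- c(0.9, 0.2, 0.2)
  st$V[2, ] <- c(0.1, 0.1, 0.1) # differences (0.8, 0.1, 0.1): shares 0.8/0.1/0.1
  st4 <- update_dimension_weights(st, phi = 0.5)
  expect_equal(st4$w, c(0.5 / 3 + 0.4, 0.5 / 3 + 0.05, 0.5 / 3 + 0.05),
    tolerance = 1e-12
  )
})

test_that("compiled and reference forward passes agree exactly", {
  tr <- fix_session()$trials
  for (variant in c("F-NS", "F-S", "F-DW", "F-Dec", "F-DW-Dec")) {
    spec <- model_spec(variant, eta = 0.3, beta = 2.5, phi = 0.6, omega = 0.85)
    a <- featrpe:::rl_forward(spec, tr, engine = "cpp")
    b <- featrpe:::rl_forward_r(spec, tr)
    expect_lt(max(abs(as.matrix(a) - as.matrix(b))), 1e-12)
  }
})

test_that("likelihood matches closed forms and floors zero probabilities", {
  tr <- fix_session()$trials
  expect_equal(
    negative_log_likelihood(model_spec("F-NS", eta = 0.3, beta = 0), tr),
    nrow(tr) * log(2)
  )
  # single trial with P(chosen) = 0.855
  one <- tr[1, ]
  p1 <- featrpe:::rl_forward(model_spec("F-NS", eta = 0.2, beta = 0), one)$p_choice
  expect_equal(negative_log_likelihood(model_spec("F-NS", eta = 0.2, beta = 0), one),
    -log(p1),
    tolerance = 1e-12
  )
  expect_equal(-log(0.855), 0.1567, tolerance = 1e-3) # frozen reference point
})

test_that("RPE stays within [-1, 1] and choice probabilities are coherent", {
  tr <- fix_trials_rpe()
  expect_true(all(tr$rpe >= -1 & tr$rpe <= 1))
  expect_true(all(tr$v_chosen >= 0 & tr$v_chosen <= 1))
  expect_true(all(tr$p_choice > 0 & tr$p_choice < 1))
})

test_that("without reversals the rewarded value converges and |RPE| shrinks", {
  # single very long block: always choose color 1, always rewarded
  trials <- tibble::tibble(
    session = 1L, block = 1L, trial = 0:199,
    color = 1L, location = 1L, motion = 1L, rewarded = 1L
  )
  spec <- model_spec("F-NS", eta = 0.3, beta = 2)
  fwd <- featrpe:::rl_forward(spec, trials)
  expect_true(all(diff(fwd$v_chosen) >= 0))
  expect_gt(tail(fwd$v_chosen, 1), 0.99)
  expect_true(all(diff(abs(fwd$rpe)) <= 1e-12))
})

test_that("fitting is seed-deterministic and AIC follows its definition", {
  ss <- generate_sessions(
    task_config(n_blocks = 5),
    function() agent_rl(model_spec("F-NS", eta = 0.35, beta = 3)),
    n_sessions = 2, seed = 31
  )
  f1 <- fit_rl("F-NS", ss$trials, seed = 4)
  f2 <- fit_rl("F-NS", ss$trials, seed = 4)
  expect_identical(f1$spec$params, f2$spec$params)
  expect_equal(f1$aic, 2 * 2 + 2 * f1$nll)
  # recovery on moderate data is already decent for the 2-parameter variant
  expect_lt(abs(f1$spec$params["eta"] - 0.35), 0.12)
})

test_that("model comparison ranks by AIC and flags disagreements on data", {
  ss <- generate_sessions(
    task_config(n_blocks = 5),
    function() agent_rl(model_spec("F-NS", eta = 0.35, beta = 3)),
    n_sessions = 2, seed = 31
  )
  fits <- lapply(c("F-NS", "F-DW-Dec"), fit_rl, trials = ss$trials, seed = 4)
  cmp <- compare_models(fits)
  expect_equal(cmp$aic, 2 * cmp$k + 2 * cmp$nll)
  expect_equal(sum(cmp$aic_best), 1L)
  expect_equal(cmp$variant[cmp$aic_best], cmp$variant[1])

  other <- generate_sessions(
    task_config(n_blocks = 5),
    function() agent_rl(model_spec("F-NS", eta = 0.35, beta = 3)),
    n_sessions = 2, seed = 99
  )
  fits2 <- list(fits[[1]], fit_rl("F-DW-Dec", other$trials, seed = 4))
  expect_error(compare_models(fits2), "same trial data")
})

test_that("block-wise cross-validation favors the generating model", {
  # moderate dimension weighting and decay, so the mismatched variants
  # (color-only F-S, unweighted F-NS) genuinely lose held-out likelihood
  gen <- model_spec("F-DW-Dec", eta = 0.3, beta = 4, phi = 0.3, omega = 0.8)
  ss <- generate_sessions(task_config(n_blocks = 8), function() agent_rl(gen),
    n_sessions = 4, seed = 61
  )
  cv_gen <- cross_validate_rl("F-DW-Dec", ss$trials, seed = 5, reps = 4)
  cv_fs <- cross_validate_rl("F-S", ss$trials, seed = 5, reps = 4)
  cv_ns <- cross_validate_rl("F-NS", ss$trials, seed = 5, reps = 4)
  expect_equal(nrow(cv_gen), 4)
  expect_gt(attr(cv_gen, "mean_test_ll"), attr(cv_fs, "mean_test_ll"))
  expect_gt(attr(cv_gen, "mean_test_ll"), attr(cv_ns, "mean_test_ll"))
  # reproducible splits
  cv_rep <- cross_validate_rl("F-DW-Dec", ss$trials, seed = 5, reps = 4)
  expect_identical(cv_gen$test_ll, cv_rep$test_ll)
  expect_error(
    cross_validate_rl("F-NS", ss$trials[ss$trials$block == 1, ], seed = 1),
    "5 blocks"
  )
})

test_that("variant parameter counts follow the model family definition", {
  expect_equal(model_spec("F-NS")$k, 2)
  expect_equal(model_spec("F-S")$k, 2)
  expect_equal(model_spec("F-DW")$k, 3)
  expect_equal(model_spec("F-Dec")$k, 3)
  expect_equal(model_spec("F-DW-Dec")$k, 4)
  expect_error(model_spec("F-NS", eta = 1.5), "out of bounds")
})
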