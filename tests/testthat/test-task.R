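test_that("a perfectly correct agent ends every block at exactly 30 trials", {
  # hand-trace of the criterion: with all-correct outcomes the 12-trial
  # running average is 1 >= 0.9 from trial 12 on, but blocks cannot end
  # before the 30-trial minimum, so the first check at trial 30 terminates
  sess <- generate_session(task_config(n_blocks = 5), agent_color_oracle(),
    seed = 7
  )
  expect_equal(sess$blocks$n_trials, rep(30L, 5))
  expect_true(all(sess$trials$rewarded == 1))
})

test_that("block lengths are always within the configured bounds", {
  sess <- generate_session(task_config(n_blocks = 8), agent_random(), seed = 3)
  expect_true(all(sess$blocks$n_trials >= 30))
  expect_true(all(sess$blocks$n_trials <= 100))
})

test_that("the same seed and agent reproduce a session exactly", {
  a <- generate_session(task_config(n_blocks = 4), agent_rl(fitted_dwdec_spec()),
    seed = 11
  )
  b <- generate_session(task_config(n_blocks = 4), agent_rl(fitted_dwdec_spec()),
    seed = 11
  )
  expect_identical(a$trials, b$trials)
})

test_that("reward is the deterministic indicator of choosing the rewarded color", {
  sess <- fix_session()
  expect_equal(
    sess$trials$rewarded,
    as.integer(sess$trials$color == sess$trials$rewarded_color)
  )
})

test_that("rewarded color alternates between consecutive blocks", {
  sess <- fix_session()
  rc <- sess$blocks$rewarded_color
  expect_true(all(rc[-1] != rc[-length(rc)]))
})

test_that("blocks longer than 30 trials never met the criterion earlier", {
  sess <- generate_session(task_config(n_blocks = 10), agent_rl(fitted_dwdec_spec()),
    seed = 23
  )
  for (b in which(sess$blocks$n_trials > 30)) {
    out <- sess$trials$rewarded[sess$trials$block == b]
    run_avg <- vapply(
      30:(length(out) - 1),
      function(t) mean(out[(t - 11):t]), numeric(1)
    )
    expect_true(all(run_avg < 0.9))
  }
})

test_that("irrelevant-dimension features are balanced for a random agent", {
  sess <- generate_sessions(task_config(n_blocks = 4), agent_random,
    n_sessions = 4, seed = 5
  )
  n <- nrow(sess$trials)
  expect_gt(n, 1000)
  ci <- 3 * sqrt(0.25 / n) # ~99.7% binomial interval around 0.5
  expect_lt(abs(mean(sess$trials$location == 1) - 0.5), ci)
  expect_lt(abs(mean(sess$trials$motion == 1) - 0.5), ci)
})

test_that("event times are strictly increasing within each trial", {
  tr <- fix_session()$trials
  expect_true(all(tr$t_stim_on < pmin(tr$t_color_on, tr$t_motion_on)))
  expect_true(all(pmax(tr$t_color_on, tr$t_motion_on) < tr$t_dim))
  expect_true(all(tr$t_dim < tr$t_outcome))
})

test_that("ideal observer declares learning early for all-correct blocks and never for all-incorrect", {
  expect_true(is.na(learning_trial(rep(0, 30))))
  lt <- learning_trial(rep(1, 30))
  expect_false(is.na(lt))
  expect_lte(lt, 10)
  expect_true(is.na(learning_trial(c(1, 1, 1)))) # below the minimum length
})

test_that("learning trial falls in the second half when learning starts there", {
  set.seed(1)
  outcomes <- c(rbinom(15, 1, 0.5), rep(1, 15))
  lt <- learning_trial(outcomes)
  expect_false(is.na(lt))
  expect_gt(lt, 15 / 2) # not declared during the chance phase
  # and with a clean chance-then-perfect split it lies in the second half
  outcomes2 <- c(rep(c(0, 1), length.out = 15), rep(1, 15))
  lt2 <- learning_trial(outcomes2)
  expect_gt(lt2, 15)
})

test_that("behavior summary matches agent construction", {
  # win-stay on color: repeats its color after every rewarded trial
  sess <- generate_session(task_config(n_blocks = 4), agent_color_wsls(),
    seed = 2
  )
  s <- behavior_summary(sess)
  expect_equal(s$p_repeat_color, 1.0)
  expect_equal(s$n_blocks, 4)

  # random agent: all repeat probabilities near 0.5
  big <- generate_sessions(task_config(n_blocks = 4), agent_random,
    n_sessions = 4, seed = 9
  )
  sb <- behavior_summary(big)
  for (p in c(sb$p_repeat_color, sb$p_repeat_location, sb$p_repeat_motion)) {
    expect_lt(abs(p - 0.5), 0.05)
  }
  # a single-trial session has undefined repeat probabilities
  single <- behavior_summary(list(trials = big$trials[1, ], blocks = big$blocks))
  expect_true(is.na(single$p_repeat_color))
})

test_that("invalid task configurations are rejected", {
  expect_error(task_config(block_len_min = 50, block_len_max = 40), "exceed")
  expect_error(task_config(criterion_window = 40), "exceed")
  expect_error(task_config(criterion_rate = 1.5), "0, 1")
})
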