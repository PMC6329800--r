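test_that("extreme-RPE selection takes floor(fraction * n) per tail with stable ties", {
  tr <- tibble::tibble(
    session = 1L, block = 1L, trial = 0:7,
    color = rep(1:2, 4), location = 1L, motion = 1L,
    rewarded = 1L, rpe = c(0.8, 0.1, 0.6, 0.3, 0.2, 0.7, 0.4, 0.5)
  )
  sets <- select_extreme_rpe_trials(tr, "pRPE")
  expect_length(sets$low, 2)
  expect_length(sets$high, 2)
  expect_equal(sets$low, c(2, 5)) # |RPE| = 0.1, 0.2
  expect_equal(sets$high, c(1, 6)) # |RPE| = 0.8, 0.7

  # all-equal RPEs: sizes still floor(0.25 n), earliest trials win by tie rule
  tr$rpe <- rep(0.5, 8)
  sets2 <- select_extreme_rpe_trials(tr, "pRPE")
  expect_equal(sets2$low, c(1, 2))
  expect_equal(sets2$high, c(7, 8))

  # too few eligible trials: neuron skipped
  expect_null(select_extreme_rpe_trials(tr[1:6, ], "pRPE"))
})

test_that("low-RPE trials concentrate late in blocks for a learning agent", {
  tr <- fix_trials_rpe()
  sets <- select_extreme_rpe_trials(tr, "pRPE")
  expect_gt(mean(tr$trial[sets$low]), mean(tr$trial[sets$high]))
})

test_that("the normalized rate change matches its closed form", {
  tr <- fix_trials_rpe()
  # synthetic spike trains with known pre/post color-onset rates on trial n+1
  mk_rec <- function(pre_hz, post_hz) {
    rows <- seq_len(nrow(tr) - 1)
    sp <- dplyr::bind_rows(lapply(rows + 1, function(i) {
      t0 <- tr$t_color_on[i]
      tibble::tibble(trial = i, t = c(
        if (pre_hz > 0) t0 - seq(0.05, 0.45, length.out = pre_hz %/% 2) else numeric(0),
        if (post_hz > 0) t0 + seq(0.05, 0.45, length.out = post_hz %/% 2) else numeric(0)
      ))
    }))
    structure(list(id = 1L, area = "ACC", spikes = sp), class = "neuron_recording")
  }
  # r_post = 2 r_pre > 0 -> delta = 1/3
  ch <- color_onset_rate_change(mk_rec(4, 8), tr, rows_n = 1:20)
  expect_equal(unique(round(ch$delta, 10)), 1 / 3)
  # r_pre = 0, r_post > 0 -> delta = 1
  ch2 <- color_onset_rate_change(mk_rec(0, 8), tr, rows_n = 1:20)
  expect_equal(unique(ch2$delta), 1)
  # both zero -> 0; equal -> 0
  ch3 <- color_onset_rate_change(mk_rec(0, 0), tr, rows_n = 1:20)
  expect_equal(unique(ch3$delta), 0)
  ch4 <- color_onset_rate_change(mk_rec(6, 6), tr, rows_n = 1:20)
  expect_equal(unique(round(ch4$delta, 10)), 0)
  # delta is invariant to common rate scaling
  expect_equal(
    color_onset_rate_change(mk_rec(4, 8), tr, rows_n = 1:20)$delta,
    color_onset_rate_change(mk_rec(8, 16), tr, rows_n = 1:20)$delta
  )
})

test_that("block-final trials are dropped because trial n+1 crosses a reversal", {
  tr <- fix_trials_rpe()
  last_of_block <- which(diff(c(tr$block, max(tr$block) + 1)) != 0)
  rec <- simulate_neuron(neuron_profile("ACC", 5), tr, seed = 2)
  ch <- color_onset_rate_change(rec, tr, rows_n = last_of_block)
  expect_equal(nrow(ch), 0)
})

test_that("the paired transfer contrast matches a textbook paired t-test", {
  low <- c(0.42, 0.31, 0.55, 0.20, 0.38)
  high <- c(0.30, 0.25, 0.41, 0.22, 0.30)
  deltas <- dplyr::bind_rows(
    tibble::tibble(
      neuron = 1:5, area = "ACC", rpe_set = "low",
      prev = "preferred", delta = low, n_pairs = 10L
    ),
    tibble::tibble(
      neuron = 1:5, area = "ACC", rpe_set = "high",
      prev = "preferred", delta = high, n_pairs = 10L
    )
  )
  res <- transfer_contrast(deltas)
  d <- low - high
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  row <- res[res$contrast == "preferred", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # identical deltas across conditions -> not evaluable (zero variance)
  deltas0 <- dplyr::mutate(deltas, delta = 0.3)
  res0 <- transfer_contrast(deltas0)
  expect_false(res0$evaluable[res0$contrast == "preferred"])
})

test_that("a planted transfer rule produces the preferred/nonpreferred asymmetry", {
  tr <- fix_trials_rpe()
  blocks <- fix_session()$blocks
  deltas <- dplyr::bind_rows(lapply(1:12, function(i) {
    prof <- neuron_profile("ACC", 3, planted_signal("transfer",
      gain = 25, dimension = "color", feature = 1,
      event = "t_color_on", latency = 0, duration = 0.5
    ))
    rec <- simulate_neuron(prof, tr, seed = 400 + i)
    rec$id <- i
    neuron_transfer_deltas(rec, tr,
      signal = "pRPE", preferred_feature = 1
    )
  }))
  res <- transfer_contrast(deltas)
  pref <- res[res$contrast == "preferred", ]
  nonpref <- res[res$contrast == "nonpreferred", ]
  expect_lt(pref$p, 0.05)
  expect_gt(pref$t, 0) # low-RPE trials show the larger color-onset response
  expect_gt(nonpref$p, 0.05)
})
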