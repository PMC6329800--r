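test_that("planted color-specific pRPE neurons are recovered with the right preferred color", {
  tr <- fix_trials_rpe()
  blocks <- fix_session()$blocks
  hits <- 0
  prefs <- integer(0)
  for (i in 1:3) {
    prof <- neuron_profile(
      "ACC", 3,
      planted_signal("pRPE",
        gain = 14, dimension = "color", feature = 1,
        latency = 0.2, duration = 0.5
      )
    )
    rec <- simulate_neuron(prof, tr, seed = 300 + i)
    rec$id <- i
    lab <- classify_neuron(rec, tr, blocks)
    fs <- lab[lab$scope == "feature" & lab$dimension == "color" &
      lab$signal == "pRPE", ]
    if (fs$flagged) {
      hits <- hits + 1
      prefs <- c(prefs, fs$preferred_feature)
      # the encoding window sits near the planted latency
      expect_lt(abs(fs$window_start_s - 0.1), 0.2)
    }
  }
  expect_gte(hits, 2)
  expect_true(all(prefs == 1L))
})

test_that("a neuron coding RPE equally for both colors is nonspecific, not color-specific", {
  tr <- fix_trials_rpe()
  blocks <- fix_session()$blocks
  prof <- neuron_profile(
    "ACC", 3,
    planted_signal("pRPE", gain = 14, latency = 0.2, duration = 0.5)
  )
  rec <- simulate_neuron(prof, tr, seed = 77)
  rec$id <- 1L
  lab <- classify_neuron(rec, tr, blocks)
  expect_true(lab$flagged[lab$scope == "nonspecific" & lab$signal == "pRPE"])
  expect_false(lab$flagged[lab$scope == "feature" & lab$signal == "pRPE" &
    lab$dimension == "color"])
})

test_that("a split with too few trials makes the dimension not evaluable", {
  tr <- fix_trials_rpe()
  set.seed(5)
  rates <- matrix(rnorm(nrow(tr) * 73, 10), nrow(tr), 73)
  attr(rates, "cfg") <- binning_config()
  mask <- seq_len(nrow(tr)) <= 35 # ~ <15 correct trials per color split
  res <- classify_feature_specific(rates, tr, "color", "pRPE", mask = mask)
  expect_false(res$evaluable)
  expect_false(res$specific)
})

test_that("finalized labels keep feature-specific and nonspecific populations disjoint", {
  mk <- function(neuron, signal, scope, flagged, dimension = NA) {
    tibble::tibble(
      neuron = neuron, area = "ACC", signal = signal, scope = scope,
      dimension = dimension, flagged = flagged, preferred_feature = NA_integer_,
      window_start_s = NA_real_, window_len_s = NA_real_, r_peak = NA_real_,
      first_run_times = list(numeric(0)), all_sig_times = list(numeric(0))
    )
  }
  labels <- dplyr::bind_rows(
    mk(1, "pRPE", "nonspecific", TRUE),
    mk(1, "pRPE", "feature", TRUE, "color"),
    mk(2, "pRPE", "nonspecific", TRUE),
    mk(2, "nRPE", "feature", TRUE, "location"),
    mk(3, "uRPE", "nonspecific", FALSE)
  )
  out <- finalize_labels(labels)
  # neuron 1: feature-specific for pRPE, so not nonspecific-only for pRPE
  expect_false(out$nonspecific_only[out$neuron == 1 & out$scope == "nonspecific"])
  # neuron 2: feature-specific only for nRPE; its pRPE nonspecific flag stands
  expect_true(out$nonspecific_only[out$neuron == 2 & out$scope == "nonspecific"])
  # a neuron may carry labels of several signal types at once
  expect_equal(sum(out$flagged[out$neuron == 2]), 2)
  # never flagged: no exclusive flag
  expect_false(any(out$nonspecific_only[out$neuron == 3]))
})

test_that("excluded neurons yield an empty label set with recorded reasons", {
  tr <- fix_trials_rpe()
  blocks <- fix_session()$blocks
  slow <- simulate_neuron(neuron_profile("VS", baseline_hz = 0.3), tr, seed = 4)
  slow$id <- 9L
  lab <- classify_neuron(slow, tr, blocks)
  expect_equal(nrow(lab), 0)
  expect_true("rate" %in% attr(lab, "inclusion")$reasons)
})

test_that("population classification returns one inclusion row per neuron", {
  tr <- fix_trials_rpe()
  blocks <- fix_session()$blocks
  pop <- simulate_population(
    dplyr::bind_rows(
      population_group(2, "ACC",
        signal = "pRPE", dimension = "color",
        feature = 1, gain = 14, baseline_hz = 3, duration = 0.5
      ),
      population_group(3, "VS")
    ),
    tr,
    seed = 12
  )
  res <- classify_population(pop$recordings, tr, blocks)
  expect_equal(nrow(res$inclusion), 5)
  expect_true(all(res$inclusion$included))
  expect_true(all(res$labels$neuron %in% 1:5))
})
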