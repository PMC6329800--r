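# Builds a rate "matrix" directly (trials x windows) with a given bin config
# attached, bypassing spike simulation where only the statistics matter.
fake_rates <- function(mat, cfg = binning_config()) {
  stopifnot(ncol(mat) == length(cfg$starts))
  attr(mat, "cfg") <- cfg
  mat
}

test_that("rank correlation maps are exact under monotone rate transforms", {
  tr <- fix_trials_rpe()[1:80, ]
  cfg <- binning_config()
  set.seed(2)
  base <- matrix(rnorm(80 * 73), 80, 73)
  base[, 30] <- tr$rpe # identical ranks as the regressor on correct trials
  m1 <- rpe_correlation_map(fake_rates(base), tr, mode = "pRPE")
  m2 <- rpe_correlation_map(fake_rates(exp(2 * base)), tr, mode = "pRPE")
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  # a bin that is a strictly monotone function of RPE has |R| = 1
  expect_equal(m1$r[30], 1)
})

test_that("maps with fewer than 15 trials are not evaluable", {
  tr <- fix_trials_rpe()[1:20, ]
  mask <- seq_len(20) <= 14
  r <- fake_rates(matrix(rnorm(20 * 73), 20, 73))
  m <- rpe_correlation_map(r, tr, mode = "pRPE", mask = mask & tr$rewarded == 1)
  expect_false(attr(m, "evaluable"))
  det <- detect_encoding(m)
  expect_false(det$encodes)
  expect_false(det$evaluable)
})

test_that("per-bin rejection is calibrated near the nominal level under the null", {
  tr <- fix_trials_rpe()
  set.seed(31)
  reps <- 40
  rej <- numeric(0)
  for (i in seq_len(reps)) {
    r <- fake_rates(matrix(rnorm(nrow(tr) * 73), nrow(tr), 73))
    m <- rpe_correlation_map(r, tr, mode = "pRPE")
    rej <- c(rej, m$p < 0.05)
  }
  expect_lt(abs(mean(rej) - 0.05), 0.012)
})

test_that("partial correlation isolates |RPE| from outcome sign", {
  tr <- fix_trials_rpe()
  n <- nrow(tr)
  set.seed(7)
  noise <- matrix(rnorm(n * 73, sd = 0.3), n, 73)
  # rate driven by |RPE| only -> strong positive partial correlation
  surprise <- noise + matrix(abs(tr$rpe), n, 73)
  m1 <- unsigned_rpe_map(fake_rates(surprise), tr)
  expect_gt(median(m1$r), 0.3)
  # rate driven by outcome sign only -> partial correlation near 0
  sign_only <- noise + matrix(ifelse(tr$rewarded == 1, 1, -1), n, 73)
  m2 <- unsigned_rpe_map(fake_rates(sign_only), tr)
  expect_lt(max(abs(m2$r)), 0.25)
  # constant rates -> R = 0
  m3 <- unsigned_rpe_map(fake_rates(matrix(1, n, 73)), tr)
  expect_true(all(m3$r == 0))
})

test_that("rank and partial-rank correlations match brute-force oracles", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(15:40, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.3 * x
    z <- sample(c(-1, 1), n, replace = TRUE)
    rates <- fake_rates(matrix(y, n, 73))
    tr <- tibble::tibble(
      session = 1L, block = 1L, trial = seq_len(n) - 1L,
      color = 1L, location = 1L, motion = 1L,
      rewarded = as.integer(z == 1), rpe = ifelse(z == 1, abs(x), -abs(x))
    )
    m <- unsigned_rpe_map(rates, tr)
    expect_lt(abs(m$r[1] - oracle_partial_spearman(y, abs(tr$rpe), z)), 1e-10)
    sp <- featrpe:::spearman_cols(matrix(y, n, 1), x)
    expect_lt(abs(sp$r - oracle_spearman(y, x)), 1e-10)
  }
})

test_that("permutation p-values agree with the t-approximation in rank", {
  tr <- fix_trials_rpe()[1:24, ]
  set.seed(4)
  r <- fake_rates(matrix(rnorm(24 * 73), 24, 73))
  r[, 10] <- r[, 10] + 5 * tr$rpe
  mt <- rpe_correlation_map(r, tr, mode = "pRPE")
  mp <- rpe_correlation_map(r, tr, mode = "pRPE", p_method = "permutation")
  expect_equal(mt$r, mp$r)
  expect_lt(mp$p[10], 0.05)
})

test_that("the run rule flags four consecutive bins but not three", {
  cfg <- binning_config()
  n_post <- sum(cfg$is_post)
  mk_map <- function(sig_post_bins, sig_pre_bins = integer(0)) {
    r <- rep(0, 73)
    p <- rep(0.5, 73)
    post_idx <- which(cfg$is_post)
    pre_idx <- which(cfg$is_pre)
    r[post_idx[sig_post_bins]] <- 0.5
    p[post_idx[sig_post_bins]] <- 0.01
    r[pre_idx[sig_pre_bins]] <- 0.5
    p[pre_idx[sig_pre_bins]] <- 0.01
    featrpe:::new_encoding_map(cfg, r, p, 50, "pRPE", 1)
  }
  expect_true(detect_encoding(mk_map(5:8))$encodes)
  expect_false(detect_encoding(mk_map(5:7))$encodes)
  # 4 post bins but 3 consecutive significant pre bins: excluded
  expect_false(detect_encoding(mk_map(5:8, sig_pre_bins = 1:3))$encodes)
  # 2 consecutive pre bins are tolerated
  expect_true(detect_encoding(mk_map(5:8, sig_pre_bins = 1:2))$encodes)
  # the reported window is the full first qualifying run
  det <- detect_encoding(mk_map(c(5:10, 20:23)))
  expect_equal(det$window_start_s, cfg$starts[which(cfg$is_post)[5]])
  expect_equal(det$window_len_s, 5 * cfg$step + cfg$window)
})

test_that("the wrong correlation sign never counts toward encoding", {
  cfg <- binning_config()
  r <- rep(0, 73)
  p <- rep(0.5, 73)
  post_idx <- which(cfg$is_post)
  r[post_idx[1:6]] <- -0.5 # significant but negative
  p[post_idx[1:6]] <- 0.001
  m <- featrpe:::new_encoding_map(cfg, r, p, 50, "pRPE", 1)
  expect_false(detect_encoding(m)$encodes)
  m_n <- featrpe:::new_encoding_map(cfg, r, p, 50, "nRPE", -1)
  expect_true(detect_encoding(m_n)$encodes)
})

test_that("the Fisher z-test matches its closed form and is antisymmetric", {
  expect_equal(fisher_z_compare(0.5, 103, 0.5, 50), 0)
  expect_equal(fisher_z_compare(0.5, 103, 0, 103),
    atanh(0.5) / sqrt(2 / 100),
    tolerance = 1e-12
  )
  expect_equal(fisher_z_compare(0.5, 103, 0, 103), 3.884, tolerance = 1e-3)
  expect_equal(
    fisher_z_compare(0.3, 40, 0.6, 60),
    -fisher_z_compare(0.6, 60, 0.3, 40)
  )
  expect_error(fisher_z_compare(0.5, 3, 0.2, 10), "exceed 3")
  expect_error(fisher_z_compare(1, 10, 0.2, 10), "strictly inside")
})

test_that("outcome encoding is detected for planted gains and not for null rates", {
  tr <- fix_trials_rpe()
  n <- nrow(tr)
  set.seed(15)
  null_rates <- fake_rates(matrix(rnorm(n * 73, 10, 2), n, 73))
  oc0 <- outcome_encoding(null_rates, tr)
  expect_false(oc0$flagged)
  gain_rates <- fake_rates(matrix(rnorm(n * 73, 10, 2), n, 73) +
    5 * matrix(tr$rewarded, n, 73))
  oc1 <- outcome_encoding(gain_rates, tr)
  expect_true(oc1$flagged)
  expect_gt(oc1$slope, 3)
  # one outcome class only -> not evaluable
  mask <- tr$rewarded == 1
  oc2 <- outcome_encoding(gain_rates, tr, mask = mask)
  expect_true(is.na(oc2$flagged))
})

test_that("inclusion thresholds are enforced at their boundaries", {
  tr <- fix_trials_rpe()
  blocks <- fix_session()$blocks
  # a 0.4 Hz neuron fails the rate floor
  slow <- simulate_neuron(neuron_profile("ACC", baseline_hz = 0.4), tr, seed = 2)
  inc <- include_neuron(slow, tr, blocks)
  expect_false(inc$include)
  expect_true("rate" %in% inc$reasons)
  # a healthy neuron passes
  ok <- simulate_neuron(neuron_profile("ACC", baseline_hz = 6), tr, seed = 2)
  expect_true(include_neuron(ok, tr, blocks)$include)
  # 39 usable trials fail the trial minimum
  few <- include_neuron(ok, tr, blocks,
    thresholds = encoding_thresholds(min_usable_trials = sum(
      include_neuron(ok, tr, blocks)$usable
    ) + 1)
  )
  expect_false(few$include)
  expect_true("trials" %in% few$reasons)
  # all blocks unlearned -> excluded
  blocks_un <- dplyr::mutate(blocks, learned = FALSE)
  inc_un <- include_neuron(ok, tr, blocks_un)
  expect_false(inc_un$include)
  expect_true("no_learned_blocks" %in% inc_un$reasons)
})
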