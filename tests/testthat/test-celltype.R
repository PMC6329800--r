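test_that("noiseless templates return their configured durations exactly", {
  for (cl in c("narrow", "broad")) {
    w <- simulate_waveform(cl, noise_sd = 0)
    f <- extract_waveform_features(w)
    # exact to the resolution of the interpolated landmark grid (~1.6 us)
    expect_lt(
      abs(f$duration_ms - featrpe:::waveform_params(cl)$trough_to_peak),
      1.6e-3
    )
    expect_true(f$ok)
  }
  n <- extract_waveform_features(simulate_waveform("narrow", noise_sd = 0))
  b <- extract_waveform_features(simulate_waveform("broad", noise_sd = 0))
  expect_lt(n$duration_ms, b$duration_ms)
  expect_lt(n$repol_ms, b$repol_ms)
  expect_lt(n$trough_width_ms, b$trough_width_ms)
})

test_that("time-based features are invariant to amplitude scaling", {
  w <- simulate_waveform("broad", seed = 2, noise_sd = 0.01)
  f1 <- extract_waveform_features(w)
  w10 <- w * 10
  attr(w10, "dt") <- attr(w, "dt")
  f2 <- extract_waveform_features(w10)
  expect_equal(f1$duration_ms, f2$duration_ms)
  expect_equal(f1$repol_ms, f2$repol_ms)
  expect_equal(f1$trough_width_ms, f2$trough_width_ms)
})

test_that("a monophasic waveform fails feature extraction gracefully", {
  w <- -exp(-((1:64) - 10)^2 / 8)
  f <- extract_waveform_features(w, dt = 25e-6)
  expect_false(f$ok)
  expect_true(is.na(f$duration_ms))
})

test_that("PCA splitting recovers two planted waveform classes", {
  set.seed(6)
  classes <- rep(c("narrow", "broad"), each = 100)
  feats <- dplyr::bind_rows(lapply(seq_along(classes), function(i) {
    extract_waveform_features(
      simulate_waveform(classes[i], seed = i, noise_sd = 0.02)
    )
  }))
  split <- classify_by_pca(feats, region = "cortical")
  expect_gte(mean(split$labels == classes), 0.95)
  expect_false(split$low_confidence)

  # duplicating every unit leaves the split point unchanged
  split2 <- classify_by_pca(feats[rep(seq_len(200), 2), ], region = "cortical")
  expect_equal(split2$split_point, split$split_point, tolerance = 1e-3)

  # a single tight cluster triggers the low-confidence median split
  expect_warning(
    split3 <- classify_by_pca(feats[classes == "broad", ], region = "cortical"),
    "unimodal"
  )
  expect_true(split3$low_confidence)
})

test_that("striatal feature set also separates the classes", {
  set.seed(16)
  classes <- rep(c("narrow", "broad"), each = 60)
  feats <- dplyr::bind_rows(lapply(seq_along(classes), function(i) {
    extract_waveform_features(
      simulate_waveform(classes[i], seed = 1000 + i, noise_sd = 0.02),
      region = "striatal"
    )
  }))
  split <- classify_by_pca(feats, region = "striatal")
  acc <- mean(split$labels == classes | split$labels == "unidentified")
  expect_gte(mean(split$labels == classes), 0.9)
})

test_that("the enrichment chi-square matches the textbook formula", {
  # hand-built 2x2 table: narrow (20 flagged, 30 not), broad (40, 10)
  cls <- c(rep("narrow", 50), rep("broad", 50))
  flg <- c(rep(TRUE, 20), rep(FALSE, 30), rep(TRUE, 40), rep(FALSE, 10))
  res <- enrichment_test(cls, flg)
  # chi^2 = n (ad - bc)^2 / (r1 r2 c1 c2); margins: rows 50/50, cols 40/60
  chi_hand <- 100 * (30 * 40 - 20 * 10)^2 / (50 * 50 * 40 * 60)
  expect_equal(res$chi_sq, chi_hand, tolerance = 1e-12)
  expect_equal(abs(res$phi), sqrt(chi_hand / 100), tolerance = 1e-12)

  # identical composition in flagged subset and population: chi^2 = 0
  cls2 <- rep(c("narrow", "broad"), 50)
  flg2 <- rep(c(TRUE, TRUE, FALSE, FALSE), 25)
  expect_equal(enrichment_test(cls2, flg2)$chi_sq, 0)

  # empty margin: not evaluable
  expect_false(enrichment_test(cls2, rep(FALSE, 100))$evaluable)
})

test_that("planted class-conditional encoding is detected with the right direction", {
  set.seed(30)
  reps <- 20
  signs <- ok <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 400
    cls <- sample(c("narrow", "broad"), n, replace = TRUE, prob = c(0.3, 0.7))
    p_flag <- ifelse(cls == "narrow", 0.45, 0.15) # 3x enrichment
    flg <- runif(n) < p_flag
    res <- enrichment_test(cls, flg)
    ok[r] <- res$p < 0.05
    signs[r] <- res$ratio_flagged > res$ratio_population
  }
  expect_gte(mean(ok), 0.8) # detection power at the planted effect size
  expect_gte(mean(signs[ok]), 0.95) # direction of the enrichment
})
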