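# Shared fixtures, memoized across test files within one run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# The generative parameter set used throughout (fitted F-DW-Dec values).
fitted_dwdec_spec <- function() {
  model_spec("F-DW-Dec", eta = 0.22, beta = 3.55, phi = 0.68, omega = 0.92)
}

# One 9-block session of F-DW-Dec behavior with its RPE trace attached.
fix_session <- function() {
  fixture("session", {
    generate_session(task_config(n_blocks = 9), agent_rl(fitted_dwdec_spec()),
      seed = 42
    )
  })
}

fix_trials_rpe <- function() {
  fixture("trials_rpe", rpe_trace(fitted_dwdec_spec(), fix_session()$trials))
}

# Brute-force Spearman: rank then Pearson, independent of the package path.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force partial rank correlation via residuals of rank regressions.
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x)
  ry <- rank(y)
  rz <- rank(z)
  ex <- resid(lm(rx ~ rz))
  ey <- resid(lm(ry ~ rz))
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# Brute-force two-sample KS statistic: max ECDF gap over all sample points.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(fa - fb))
}

# Direct window-count binning oracle.
oracle_bin_rates <- function(spikes, trials, cfg) {
  out <- matrix(0, nrow(trials), length(cfg$starts))
  for (tr in seq_len(nrow(trials))) {
    s <- spikes$t[spikes$trial == tr] - trials[[cfg$event]][tr]
    for (b in seq_along(cfg$starts)) {
      out[tr, b] <- sum(s >= cfg$starts[b] & s < cfg$starts[b] + cfg$window)
    }
  }
  out / cfg$window
}
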