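#' Pooled latency distribution of encoding times
#'
#' Pools encoding-window times over the flagged neurons of a group and builds
#' the normalized cumulative distribution. Two pooling modes: `"first_run"`
#' uses only each neuron's first run of consecutive significant windows (the
#' mode used for latency comparisons) and `"all_bins"` pools every
#' significant post-outcome window (the mode used for the population
#' histograms).
#'
#' @param labels Finalized label tibble ([finalize_labels()]) filtered to the
#'   rows to pool (flagged rows contribute their window times).
#' @param group Optional column name used to split into groups; `NULL` pools
#'   everything into one group `"all"`.
#' @param mode `"first_run"` or `"all_bins"`.
#' @return A tibble of class `latency_distribution`: per group and pooled
#'   window time, `n` (bins at that time), `cum` (normalized cumulative sum),
#'   plus per-neuron times kept in attribute `by_neuron` for randomization
#'   tests.
#' @export
latency_distribution <- function(labels, group = NULL, mode = c("first_run", "all_bins")) {
  mode <- match.arg(mode)
  col <- if (mode == "first_run") "first_run_times" else "all_sig_times"
  rows <- labels[labels$flagged, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("No flagged neurons to pool.", call. = FALSE)
  }
  rows$group <- if (is.null(group)) "all" else as.character(rows[[group]])
  by_neuron <- lapply(seq_len(nrow(rows)), function(i) rows[[col]][[i]])
  names(by_neuron) <- rows$group

  pooled <- rows |>
    dplyr::select("group", times = dplyr::all_of(col)) |>
    tidyr::unnest("times") |>
    dplyr::count(.data$group, time = .data$times) |>
    dplyr::arrange(.data$group, .data$time) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(cum = cumsum(.data$n) / sum(.data$n)) |>
    dplyr::ungroup()
  structure(pooled,
    class = c("latency_distribution", class(pooled)),
    by_neuron = by_neuron, mode = mode
  )
}

#' Time at which a fraction of a signal is encoded
#'
#' The earliest pooled window time whose normalized cumulative sum reaches
#' `q` (the "25% crossing" with the default).
#'
#' @param dist A [latency_distribution()] (or a numeric vector of pooled
#'   times).
#' @param q Crossing fraction.
#' @return Named numeric vector, one crossing time per group.
#' @export
latency_quantile <- function(dist, q = 0.25) {
  if (is.numeric(dist)) {
    tt <- sort(dist)
    return(tt[ceiling(q * length(tt))])
  }
  vapply(split(dist, dist$group), function(d) {
    d$time[which(d$cum >= q)[1]]
  }, numeric(1))
}

#' Pairwise latency-distribution comparisons
#'
#' Two-sample Kolmogorov-Smirnov tests on the pooled encoding-time
#' distributions of every group pair, with Bonferroni-Holm step-down
#' correction, plus companion Wilcoxon rank-sum tests.
#'
#' @param dist A [latency_distribution()] with at least two groups.
#' @param alpha Family-wise error level.
#' @return Tibble: `group1`, `group2`, `D`, `p_ks`, `p_ks_holm`, `W`,
#'   `p_rs`, `p_rs_holm`, `significant` (Holm-corrected KS decision).
#' @export
compare_latencies_ks <- function(dist, alpha = 0.05) {
  samples <- lapply(
    split(dist, dist$group),
    function(d) rep(d$time, d$n)
  )
  groups <- names(samples)
  if (length(groups) < 2) {
    stop("Need at least two groups.", call. = FALSE)
  }
  if (any(vapply(samples, length, integer(1)) < 2)) {
    stop("Each group needs at least 2 pooled times.", call. = FALSE)
  }
  pairs <- utils::combn(groups, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- samples[[pairs[1, i]]]
    b <- samples[[pairs[2, i]]]
    ks <- suppressWarnings(ks.test(a, b))
    rs <- suppressWarnings(wilcox.test(a, b))
    tibble::tibble(
      group1 = pairs[1, i], group2 = pairs[2, i],
      D = unname(ks$statistic), p_ks = ks$p.value,
      W = unname(rs$statistic), p_rs = rs$p.value
    )
  })
  out <- dplyr::bind_rows(out)
  out$p_ks_holm <- p.adjust(out$p_ks, method = "holm")
  out$p_rs_holm <- p.adjust(out$p_rs, method = "holm")
  out$significant <- out$p_ks_holm < alpha
  out[, c(
    "group1", "group2", "D", "p_ks", "p_ks_holm", "W", "p_rs",
    "p_rs_holm", "significant"
  )]
}

#' Randomization test for a difference in latency quantile crossings
#'
#' Tests whether the time at which a fraction `q` of the pooled signal is
#' encoded differs between two groups. Neurons (with their full multisets of
#' encoding times) are permuted between the groups `n` times; the two-sided
#' p-value is `(b + 1) / (n + 1)` where `b` counts null statistics at least
#' as extreme as the observed crossing-time difference.
#'
#' @param times_a,times_b Lists of per-neuron encoding-time vectors.
#' @param q Crossing fraction.
#' @param n Number of permutations.
#' @param seed Integer seed.
#' @return One-row tibble: `observed` (crossing difference a - b, s),
#'   `crossing_a`, `crossing_b`, `p`, `n_perm`.
#' @export
quantile_crossing_test <- function(times_a, times_b, q = 0.25, n = 500, seed = 1) {
  stopifnot(length(times_a) >= 1, length(times_b) >= 1)
  set.seed(as.integer(seed))
  qa <- latency_quantile(unlist(times_a), q)
  qb <- latency_quantile(unlist(times_b), q)
  obs <- qa - qb
  all_neurons <- c(times_a, times_b)
  na <- length(times_a)
  null <- vapply(seq_len(n), function(i) {
    idx <- sample(length(all_neurons), na)
    latency_quantile(unlist(all_neurons[idx]), q) -
      latency_quantile(unlist(all_neurons[-idx]), q)
  }, numeric(1))
  p <- (sum(abs(null) >= abs(obs) - 1e-12) + 1) / (n + 1)
  tibble::tibble(
    observed = obs, crossing_a = qa, crossing_b = qb, p = p, n_perm = n
  )
}
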