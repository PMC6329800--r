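#' Bootstrap test for dimension-preferential feature-specific encoding
#'
#' Tests whether feature-specific RPE encoding of one signal type is more
#' prevalent for some stimulus dimension (color vs location vs motion) than
#' expected from the population of all feature-specific RPE neurons,
#' regardless of their dimension. The null model treats dimension labels as
#' exchangeable: each bootstrap replicate reassigns every flagged
#' (neuron, dimension) unit a dimension drawn uniformly from the three, and a
#' dimension is flagged when its observed proportion (flags / neurons in
#' scope) exceeds the 95th percentile of its null proportions (one-sided).
#'
#' @param labels Finalized label tibble ([finalize_labels()]).
#' @param neurons Tibble of the neurons in scope (columns `neuron`, `area`) —
#'   typically the included neurons; the denominator of all proportions.
#' @param signal `"pRPE"`, `"nRPE"` or `"uRPE"`.
#' @param n Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param by_area Also run the test separately within each area.
#' @return Tibble: `area` (`"all"` for pooled), `dimension`, `n_flagged`,
#'   `proportion`, `null_q95`, `flagged`.
#' @export
prevalence_bootstrap <- function(labels, neurons, signal, n = 10000, seed = 1,
                                 by_area = FALSE) {
  fs <- labels[labels$scope == "feature" & labels$flagged &
    labels$signal == signal, c("neuron", "area", "dimension")]
  if (nrow(fs) == 0) {
    stop("No feature-specific neurons in scope for signal ", signal,
      call. = FALSE
    )
  }
  scopes <- list(all = list(fs = fs, n_scope = nrow(neurons)))
  if (by_area) {
    for (a in sort(unique(neurons$area))) {
      scopes[[a]] <- list(
        fs = fs[fs$area == a, , drop = FALSE],
        n_scope = sum(neurons$area == a)
      )
    }
  }
  dims <- c("color", "location", "motion")
  set.seed(as.integer(seed))
  out <- lapply(names(scopes), function(sc) {
    s <- scopes[[sc]]
    k <- nrow(s$fs)
    if (k == 0 || s$n_scope == 0) {
      return(NULL)
    }
    obs <- vapply(dims, function(d) sum(s$fs$dimension == d), numeric(1))
    # exchangeable-dimension null: uniform reassignment of the k units
    null_counts <- matrix(
      tabulate(sample.int(3, k * n, replace = TRUE) +
        3 * rep(seq_len(n) - 1, each = k), 3 * n),
      nrow = n, byrow = TRUE
    )
    q95 <- apply(null_counts / s$n_scope, 2, quantile, probs = 0.95)
    tibble::tibble(
      area = sc, dimension = dims, n_flagged = obs,
      proportion = obs / s$n_scope, null_q95 = q95,
      flagged = obs / s$n_scope > q95
    )
  })
  dplyr::bind_rows(out)
}

#' Color-tuning index
#'
#' `I_col = (P_col - (P_loc + P_mot) / 2) / (P_col + P_loc + P_mot)` —
#' the relative prevalence of color-specific over location-/motion-specific
#' RPE encoding. Ranges from -0.5 (no color specificity) to 1 (only color);
#' 0 when the three dimensions are equally prevalent.
#'
#' @param p_col,p_loc,p_mot Proportions of color-/location-/motion-specific
#'   RPE neurons.
#' @return The index; `NA` when all three proportions are zero.
#' @examples
#' color_tuning_index(0.2, 0.1, 0.1) # 0.25
#' @export
color_tuning_index <- function(p_col, p_loc, p_mot) {
  tot <- p_col + p_loc + p_mot
  ifelse(tot == 0, NA_real_, (p_col - (p_loc + p_mot) / 2) / tot)
}

#' Area differences in color tuning by label randomization
#'
#' Computes each area's color-tuning index from its feature-specific flags,
#' then builds a null distribution by shuffling area labels across neurons
#' (`n` replicates, area sizes preserved — each neuron carries its flag set
#' with it). An area is significant when its observed index falls outside
#' the two-sided 95% interval of its null indices.
#'
#' @inheritParams prevalence_bootstrap
#' @return Tibble: `area`, `n_neurons`, `i_col`, `ci_lo`, `ci_hi`,
#'   `significant`.
#' @export
tuning_index_area_test <- function(labels, neurons, signal, n = 10000, seed = 1) {
  areas <- sort(unique(neurons$area))
  if (length(areas) < 2) {
    stop("Need at least two areas.", call. = FALSE)
  }
  fs <- labels[labels$scope == "feature" & labels$flagged &
    labels$signal == signal, c("neuron", "dimension")]
  dims <- c("color", "location", "motion")
  # per-neuron flag counts per dimension
  flag_mat <- vapply(dims, function(d) {
    as.numeric(neurons$neuron %in% fs$neuron[fs$dimension == d])
  }, numeric(nrow(neurons)))

  icol_by_area <- function(area_labels) {
    vapply(areas, function(a) {
      m <- area_labels == a
      p <- colSums(flag_mat[m, , drop = FALSE]) / sum(m)
      color_tuning_index(p[1], p[2], p[3])
    }, numeric(1))
  }
  observed <- icol_by_area(neurons$area)
  set.seed(as.integer(seed))
  null <- t(vapply(
    seq_len(n),
    function(i) icol_by_area(sample(neurons$area)),
    numeric(length(areas))
  ))
  ci <- apply(null, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  tibble::tibble(
    area = areas,
    n_neurons = as.integer(table(factor(neurons$area, levels = areas))),
    i_col = unname(observed),
    ci_lo = ci[1, ], ci_hi = ci[2, ],
    significant = !is.na(observed) &
      (observed < ci[1, ] | observed > ci[2, ])
  )
}
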