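#' Split neurons into putative cell classes by waveform shape
#'
#' Standardizes two waveform features — trough-to-peak duration and time to
#' repolarization for cortical areas, trough width and ISVD for striatal
#' areas — projects units onto the first principal component, and splits at
#' the antimode of the PC1 distribution (the kernel-density minimum between
#' the two largest modes). Labels are oriented so `"narrow"` has the shorter
#' duration. A unimodal PC1 distribution triggers a warning, a median split
#' and a low-confidence flag. For the striatal feature set, units farther
#' than `sd_max` standardized units from both cluster centroids are labelled
#' `"unidentified"`.
#'
#' @param features Tibble of [extract_waveform_features()] rows (one per
#'   unit).
#' @param region `"cortical"` (duration + repolarization) or `"striatal"`
#'   (trough width + ISVD).
#' @param sd_max Outlier radius for the striatal "unidentified" class.
#' @return A list of class `celltype_split`: `labels` (per-unit class:
#'   `"narrow"`, `"broad"`, or `"unidentified"`), `pc1`, `split_point`,
#'   `low_confidence`, `feature_cols`.
#' @export
classify_by_pca <- function(features, region = c("cortical", "striatal"),
                            sd_max = 2) {
  region <- match.arg(region)
  cols <- if (region == "cortical") {
    c("duration_ms", "repol_ms")
  } else {
    c("trough_width_ms", "isvd")
  }
  x <- as.matrix(features[, cols])
  ok <- complete.cases(x)
  if (sum(ok) < 20) {
    stop("Need at least 20 units with valid features.", call. = FALSE)
  }
  xs <- scale(x[ok, , drop = FALSE])
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  pc1 <- pc$x[, 1]

  sp <- pc1_antimode(pc1)
  cls <- ifelse(pc1 <= sp$split, "A", "B")
  # orient: narrow = shorter duration (or narrower trough)
  dur_col <- if (region == "cortical") "duration_ms" else "trough_width_ms"
  durs <- x[ok, dur_col]
  a_narrow <- mean(durs[cls == "A"]) < mean(durs[cls == "B"])
  labels_ok <- ifelse(cls == "A",
    if (a_narrow) "narrow" else "broad",
    if (a_narrow) "broad" else "narrow"
  )

  if (region == "striatal") {
    dists <- lapply(c("narrow", "broad"), function(cl) {
      m <- labels_ok == cl
      if (sum(m) < 2) {
        return(NULL)
      }
      centroid <- colMeans(xs[m, , drop = FALSE])
      sqrt(rowSums(sweep(xs, 2, centroid)^2))
    })
    if (!any(vapply(dists, is.null, logical(1)))) {
      far <- dists[[1]] > sd_max & dists[[2]] > sd_max
      labels_ok[far] <- "unidentified"
    }
  }
  labels <- rep(NA_character_, nrow(features))
  labels[!ok] <- "unidentified"
  labels[ok] <- labels_ok
  pc1_full <- rep(NA_real_, nrow(features))
  pc1_full[ok] <- pc1
  structure(
    list(
      labels = labels, pc1 = pc1_full, split_point = sp$split,
      low_confidence = sp$low_confidence, feature_cols = cols
    ),
    class = "celltype_split"
  )
}

# Antimode of a 1-d sample: kernel-density minimum between the two largest
# modes; median with a warning if the density is unimodal. The bandwidth is
# a fixed fraction of the sample SD, so duplicating units leaves the split
# unchanged.
pc1_antimode <- function(x) {
  d <- density(x, bw = 0.2 * sd(x))
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  unimodal <- length(peaks) < 2
  if (!unimodal) {
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)[1:2]])
    valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
    # the valley must be substantially lower than both modes, otherwise the
    # "modes" are sampling wiggles of a unimodal distribution
    unimodal <- y[valley] > 0.8 * min(y[top2])
  }
  if (unimodal) {
    warning("PC1 distribution looks unimodal; splitting at the median.",
      call. = FALSE
    )
    return(list(split = median(x), low_confidence = TRUE))
  }
  list(split = d$x[valley], low_confidence = FALSE)
}

#' @export
print.celltype_split <- function(x, ...) {
  cat(sprintf(
    "<celltype_split> %s: %s%s\n",
    paste(x$feature_cols, collapse = " + "),
    paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
      collapse = ", "
    ),
    if (x$low_confidence) " (low confidence)" else ""
  ))
  invisible(x)
}

#' Cell-class enrichment of an encoding property
#'
#' Chi-square test of whether the narrow/broad composition among flagged
#' neurons differs from the composition of the whole population (2 x 2 table
#' class x flag, without continuity correction), with the phi coefficient as
#' effect size.
#'
#' @param class_labels Character vector of cell classes (`"narrow"` /
#'   `"broad"`; other labels are dropped).
#' @param flags Logical vector, same length: does the unit carry the encoding
#'   property?
#' @return One-row tibble: `chi_sq`, `p`, `phi`, `ratio_flagged`,
#'   `ratio_population` (narrow/broad ratios), `n`, `evaluable`.
#' @export
enrichment_test <- function(class_labels, flags) {
  stopifnot(length(class_labels) == length(flags))
  keep <- class_labels %in% c("narrow", "broad") & !is.na(flags)
  cl <- factor(class_labels[keep], levels = c("narrow", "broad"))
  fl <- factor(flags[keep], levels = c(FALSE, TRUE))
  tab <- table(cl, fl)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(
      chi_sq = NA_real_, p = NA_real_, phi = NA_real_,
      ratio_flagged = NA_real_, ratio_population = NA_real_,
      n = sum(keep), evaluable = FALSE
    ))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  phi <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
    sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  tibble::tibble(
    chi_sq = unname(ct$statistic), p = ct$p.value, phi = unname(phi),
    ratio_flagged = tab["narrow", "TRUE"] / tab["broad", "TRUE"],
    ratio_population = sum(tab["narrow", ]) / sum(tab["broad", ]),
    n = sum(keep), evaluable = TRUE
  )
}
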