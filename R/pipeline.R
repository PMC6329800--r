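#' Pipeline run configuration
#'
#' Bundles every stage's configuration with a master seed. Each stochastic
#' stage derives its own seed deterministically from the master seed and the
#' stage's position, so any two runs with the same configuration and seed
#' produce identical outputs. Defaults describe the study conditions: the
#' F-DW-Dec agent at the fitted parameter set eta = 0.22, beta = 3.55,
#' phi = 0.68, omega = 0.92, nine reversal blocks per session, and a small
#' demonstration population with planted feature-specific RPE neurons.
#'
#' @param task A [task_config()].
#' @param agent_spec The generative [model_spec()] for behavior.
#' @param n_sessions Number of simulated sessions.
#' @param variants Model variants to fit and compare.
#' @param cv_reps Cross-validation repetitions per variant (0 skips CV).
#' @param population Tibble of [population_group()] rows.
#' @param binning A [binning_config()].
#' @param thresholds An [encoding_thresholds()].
#' @param master_seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(task = task_config(),
                            agent_spec = model_spec("F-DW-Dec",
                              eta = 0.22, beta = 3.55,
                              phi = 0.68, omega = 0.92
                            ),
                            n_sessions = 1,
                            variants = c(
                              "F-NS", "F-S", "F-DW", "F-Dec",
                              "F-DW-Dec"
                            ),
                            cv_reps = 0,
                            population = default_population(),
                            binning = binning_config(),
                            thresholds = encoding_thresholds(),
                            master_seed = 1L) {
  structure(
    list(
      task = task, agent_spec = agent_spec, n_sessions = n_sessions,
      variants = variants, cv_reps = cv_reps, population = population,
      binning = binning, thresholds = thresholds,
      master_seed = as.integer(master_seed)
    ),
    class = "run_config"
  )
}

# Demonstration population: planted feature-specific and nonspecific RPE
# neurons across two areas plus pure-noise neurons.
default_population <- function() {
  dplyr::bind_rows(
    population_group(4, "ACC",
      signal = "pRPE", dimension = "color", feature = 1,
      gain = 8, latency = 0.15, latency_sd = 0.03
    ),
    population_group(4, "VS",
      signal = "uRPE", dimension = "color", feature = 2,
      gain = 8, latency = 0.25, latency_sd = 0.03
    ),
    population_group(3, "ACC", signal = "pRPE", gain = 6, latency = 0.15),
    population_group(3, "VS", signal = "outcome", gain = 5, latency = 0.1),
    population_group(10, "ACC"),
    population_group(10, "VS")
  )
}

stage_names <- c(
  "simulate-behavior", "fit-models", "simulate-ephys", "classify",
  "population-stats", "transfer", "celltype", "report"
)

# Deterministic per-stage seed derived from the master seed.
stage_seed <- function(master_seed, stage) {
  i <- match(stage, stage_names)
  (as.integer(master_seed) * 97L + i * 10007L) %% 2147483647L
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in order — simulate-behavior, fit-models,
#' simulate-ephys, classify, population-stats, transfer, celltype, report —
#' writing each stage's tables as tab-separated text under `out_dir` and a
#' JSON run report aggregating the headline statistics with the seeds used.
#' Later stages read their inputs from the in-memory state of earlier stages
#' within the same call; when a stage is requested without its upstream stage
#' an explicit dependency error names the missing stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Stages to run (defaults to all, in canonical order).
#' @return Invisibly, a list with the stage outputs (`trials`, `blocks`,
#'   `fits`, `comparison`, `recordings`, `truth`, `labels`, `inclusion`,
#'   `population_stats`, `transfer`, `celltype`, `report`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, stages = stage_names) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, stage_names, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- list()
  need <- function(field, producer) {
    if (is.null(st[[field]])) {
      stop(sprintf("Stage requires '%s'; run stage '%s' first.", field, producer),
        call. = FALSE
      )
    }
  }
  ms <- config$master_seed

  if ("simulate-behavior" %in% stages) {
    ss <- generate_sessions(
      config$task, function() agent_rl(config$agent_spec),
      n_sessions = config$n_sessions,
      seed = stage_seed(ms, "simulate-behavior")
    )
    st$trials <- ss$trials
    st$blocks <- ss$blocks
    write_trials(st$trials, file.path(out_dir, "trials.tsv"))
    readr::write_tsv(st$blocks, file.path(out_dir, "blocks.tsv"))
  }

  if ("fit-models" %in% stages) {
    need("trials", "simulate-behavior")
    seed <- stage_seed(ms, "fit-models")
    st$fits <- lapply(config$variants, function(v) {
      fit <- fit_rl(v, st$trials, seed = seed)
      if (config$cv_reps > 0) {
        fit$cv <- cross_validate_rl(v, st$trials,
          seed = seed,
          reps = config$cv_reps
        )
      }
      fit
    })
    names(st$fits) <- config$variants
    st$comparison <- compare_models(st$fits)
    readr::write_tsv(st$comparison, file.path(out_dir, "model_comparison.tsv"))
    best <- st$fits[[st$comparison$variant[1]]]
    write_model_fit(best, file.path(out_dir, "best_fit.json"))
    st$trials <- rpe_trace(best$spec, st$trials)
    write_trials(st$trials, file.path(out_dir, "trials_rpe.tsv"))
  }

  if ("simulate-ephys" %in% stages) {
    need("trials", "simulate-behavior")
    if (!"rpe" %in% names(st$trials)) need("fits", "fit-models")
    pop <- simulate_population(config$population, st$trials,
      seed = stage_seed(ms, "simulate-ephys")
    )
    st$recordings <- pop$recordings
    st$truth <- pop$truth
    write_spikes(st$recordings, file.path(out_dir, "spikes.tsv"))
    write_waveforms(st$recordings, file.path(out_dir, "waveforms.tsv"))
    readr::write_tsv(st$truth, file.path(out_dir, "ground_truth.tsv"))
  }

  if ("classify" %in% stages) {
    need("recordings", "simulate-ephys")
    res <- classify_population(st$recordings, st$trials, st$blocks,
      cfg = config$binning, thresholds = config$thresholds
    )
    st$labels <- res$labels
    st$inclusion <- res$inclusion
    write_labels(st$labels, file.path(out_dir, "labels.tsv"))
    readr::write_tsv(st$inclusion, file.path(out_dir, "inclusion.tsv"))
  }

  if ("population-stats" %in% stages) {
    need("labels", "classify")
    seed <- stage_seed(ms, "population-stats")
    st$population_stats <- population_stats(
      st$labels, st$inclusion,
      seed = seed
    )
    for (nm in names(st$population_stats)) {
      readr::write_tsv(
        st$population_stats[[nm]],
        file.path(out_dir, paste0(nm, ".tsv"))
      )
    }
  }

  if ("transfer" %in% stages) {
    need("labels", "classify")
    st$transfer <- transfer_stage(st$recordings, st$trials, st$blocks, st$labels,
      thresholds = config$thresholds
    )
    readr::write_tsv(st$transfer$deltas, file.path(out_dir, "transfer_deltas.tsv"))
    readr::write_tsv(st$transfer$tests, file.path(out_dir, "transfer_tests.tsv"))
  }

  if ("celltype" %in% stages) {
    need("labels", "classify")
    st$celltype <- celltype_stage(st$recordings, st$labels)
    readr::write_tsv(st$celltype$classes, file.path(out_dir, "celltype_classes.tsv"))
    readr::write_tsv(st$celltype$enrichment, file.path(out_dir, "celltype_enrichment.tsv"))
  }

  if ("report" %in% stages) {
    report <- list(
      master_seed = ms,
      stage_seeds = setNames(
        lapply(stage_names, stage_seed, master_seed = ms),
        stage_names
      ),
      n_trials = if (!is.null(st$trials)) nrow(st$trials) else NULL,
      n_blocks = if (!is.null(st$blocks)) nrow(st$blocks) else NULL,
      frac_learned = if (!is.null(st$blocks)) mean(st$blocks$learned) else NULL,
      model_comparison = st$comparison,
      n_neurons = if (!is.null(st$recordings)) length(st$recordings) else NULL,
      n_included = if (!is.null(st$inclusion)) sum(st$inclusion$included) else NULL,
      frac_feature_specific = if (!is.null(st$labels) && nrow(st$labels)) {
        fs <- unique(st$labels$neuron[st$labels$scope == "feature" & st$labels$flagged])
        length(fs) / length(unique(st$labels$neuron))
      } else {
        NULL
      },
      transfer = if (!is.null(st$transfer)) st$transfer$tests else NULL,
      celltype = if (!is.null(st$celltype)) st$celltype$enrichment else NULL
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
    st$report <- report
  }
  invisible(st)
}

# Latency distributions + tests and prevalence/tuning tables.
population_stats <- function(labels, inclusion, seed, n_boot = 2000,
                             n_perm = 500) {
  out <- list()
  rpe_rows <- labels[labels$signal != "outcome", , drop = FALSE]
  grp <- dplyr::mutate(
    rpe_rows,
    class = dplyr::case_when(
      scope == "feature" & flagged ~ "feature_specific",
      scope == "nonspecific" & nonspecific_only ~ "nonspecific",
      TRUE ~ NA_character_
    )
  )
  grp <- grp[!is.na(grp$class), , drop = FALSE]
  oc <- labels[labels$signal == "outcome" & labels$flagged, , drop = FALSE]
  if (nrow(oc)) {
    oc$class <- "outcome"
    grp <- dplyr::bind_rows(grp, oc)
  }
  if (nrow(grp[grp$flagged, ]) > 0) {
    dist <- latency_distribution(grp, group = "class", mode = "first_run")
    out$latency <- tibble::as_tibble(dist)
    if (length(unique(dist$group)) >= 2) {
      out$latency_tests <- compare_latencies_ks(dist)
    }
  }
  neurons <- inclusion[inclusion$included, c("neuron", "area")]
  prev <- lapply(c("pRPE", "nRPE", "uRPE"), function(sg) {
    res <- tryCatch(
      prevalence_bootstrap(labels, neurons, sg,
        n = n_boot, seed = seed,
        by_area = TRUE
      ),
      error = function(e) NULL
    )
    if (!is.null(res)) res$signal <- sg
    res
  })
  prev <- dplyr::bind_rows(prev)
  if (nrow(prev)) out$prevalence <- prev
  tun <- lapply(c("pRPE", "nRPE", "uRPE"), function(sg) {
    res <- tryCatch(
      tuning_index_area_test(labels, neurons, sg, n = n_boot, seed = seed),
      error = function(e) NULL
    )
    if (!is.null(res)) res$signal <- sg
    res
  })
  tun <- dplyr::bind_rows(tun)
  if (nrow(tun)) out$tuning <- tun
  out
}

# Attention-transfer stage over color-specific RPE neurons.
transfer_stage <- function(recordings, trials, blocks, labels,
                           thresholds = encoding_thresholds()) {
  cs <- labels[labels$scope == "feature" & labels$flagged &
    labels$dimension == "color", , drop = FALSE]
  ids <- vapply(recordings, function(r) r$id %||% NA_integer_, numeric(1))
  deltas <- dplyr::bind_rows(lapply(seq_len(nrow(cs)), function(i) {
    rec <- recordings[[match(cs$neuron[i], ids)]]
    inc <- include_neuron(rec, trials, blocks, thresholds)
    d <- neuron_transfer_deltas(
      rec, trials, cs$signal[i], cs$preferred_feature[i],
      mask = inc$usable
    )
    if (!is.null(d)) d$signal <- cs$signal[i]
    d
  }))
  tests <- if (nrow(deltas)) {
    dplyr::bind_rows(lapply(split(deltas, deltas$signal), function(d) {
      res <- transfer_contrast(d)
      res$signal <- d$signal[1]
      res
    }))
  } else {
    tibble::tibble()
  }
  list(deltas = deltas, tests = tests)
}

# Waveform cell-typing stage; cortical and striatal areas are split with
# their respective feature pairs.
celltype_stage <- function(recordings, labels) {
  ids <- vapply(recordings, function(r) r$id %||% NA_integer_, numeric(1))
  areas <- vapply(recordings, function(r) r$area %||% NA_character_, character(1))
  feats <- dplyr::bind_rows(lapply(recordings, function(r) {
    extract_waveform_features(r$waveform)
  }))
  feats$neuron <- ids
  feats$area <- areas
  region_of <- function(a) if (a %in% c("CD", "VS")) "striatal" else "cortical"
  feats$region <- vapply(feats$area, region_of, character(1))

  fs_ids <- unique(labels$neuron[labels$scope == "feature" & labels$flagged])
  classes <- lapply(split(feats, feats$region), function(f) {
    cl <- tryCatch(suppressWarnings(classify_by_pca(f, region = f$region[1])),
      error = function(e) NULL
    )
    if (is.null(cl)) {
      return(NULL)
    }
    tibble::tibble(
      neuron = f$neuron, area = f$area, region = f$region,
      class = cl$labels, pc1 = cl$pc1,
      low_confidence = cl$low_confidence
    )
  })
  classes <- dplyr::bind_rows(classes)
  enrichment <- if (nrow(classes)) {
    dplyr::bind_rows(lapply(
      split(classes, classes$region),
      function(cc) {
        res <- enrichment_test(cc$class, cc$neuron %in% fs_ids)
        res$region <- cc$region[1]
        res
      }
    ))
  } else {
    tibble::tibble()
  }
  list(classes = classes, enrichment = enrichment)
}
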