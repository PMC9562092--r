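#' Pipeline configuration
#'
#' One nested configuration for the whole analysis chain. Defaults mirror
#' the blocked decision experiment the package emulates: 250 Hz, 1-40 Hz
#' band-pass, 0-3.5 s decision epochs, five canonical bands, a 16/16
#' accuracy split, and the theta-band midline clustering coefficient as the
#' designated metric tied to behavior.
#'
#' @param synth A [synth_config()].
#' @param preprocess List: `target_fs`, `lo`, `hi`, `tmin`, `tmax`,
#'   `peak_to_peak_max`, `filter_method` (the pipeline defaults to the
#'   spectral zero-phase Butterworth for throughput on long cohorts).
#' @param microstate List: `k_min`, `k_max`, `polarity`, `min_separation_ms`.
#' @param erp List: `electrodes`, `component`, `alpha`, `min_run_ms`.
#' @param connectivity List: `bands`, `seg_len_s`.
#' @param stats List: `split_k`, `metric` (`"cc_mean"`, `"le_mean"`, `"ge"`,
#'   `"cpl"`), `metric_band`, `midline_metric` (use the midline-electrode
#'   mean of the per-node metric instead of the whole-brain mean).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            preprocess = list(),
                            microstate = list(),
                            erp = list(),
                            connectivity = list(),
                            stats = list()) {
  cfg <- list(
    synth = synth,
    preprocess = utils::modifyList(
      list(target_fs = synth$fs, lo = 1, hi = 40, tmin = 0, tmax = 3.5,
           peak_to_peak_max = 200, filter_method = "fft"), preprocess),
    microstate = utils::modifyList(
      list(k_min = 2, k_max = 8, polarity = "sensitive",
           min_separation_ms = 10), microstate),
    erp = utils::modifyList(
      list(electrodes = c("FP1", "FPz", "FP2", "AF3", "AF4"),
           component = "P2", alpha = 0.05, min_run_ms = 20), erp),
    connectivity = utils::modifyList(
      list(bands = names(eeg_bands()), seg_len_s = 1), connectivity),
    stats = utils::modifyList(
      list(split_k = 16, metric = "cc_mean", metric_band = "theta",
           midline_metric = TRUE), stats)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Per-stage sections (`synth`, `preprocess`, `microstate`, `erp`,
#' `connectivity`, `stats`) override the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(synth_args$coupling_spec)) {
    synth_args$coupling_spec <- tibble::as_tibble(synth_args$coupling_spec)
  }
  for (nm in c("p2_amplitudes", "p2_latency", "rt_mean", "valence_shift")) {
    if (!is.null(synth_args[[nm]])) synth_args[[nm]] <- unlist(synth_args[[nm]])
  }
  pipeline_config(
    synth = do.call(synth_config, synth_args),
    preprocess = y$preprocess %||% list(),
    microstate = y$microstate %||% list(),
    erp = y$erp %||% list(),
    connectivity = y$connectivity %||% list(),
    stats = y$stats %||% list()
  )
}

# Midline or whole-brain summary of one block/band metrics row.
designated_metric <- function(metrics_row, cfg_stats, labels) {
  metric <- cfg_stats$metric
  if (metric %in% c("ge", "cpl")) return(metrics_row[[metric]])
  vec_name <- sub("_mean$", "", metric)
  v <- metrics_row[[vec_name]][[1]]
  if (isTRUE(cfg_stats$midline_metric)) {
    mid <- labels[labels %in% c("FPz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "Oz")]
    v <- v[names(v) %in% mid]
  }
  mean(v)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: synthetic-data generation (per subject), signal
#' conditioning and epoching, per-condition microstate analysis on the
#' grand-average ERP, prefrontal ERP component measurement with pointwise
#' ANOVA, per-block band-wise PSI connectivity, percolation-sparsified
#' graph metrics, behavioral/subjective generation tied to the designated
#' metric, and the statistics layer (paired t on valence, ANOVA on
#' behavior, accuracy split with Welch t on local measures, Pearson
#' correlations of global and designated local measures with accuracy,
#' topographic summary). All stages are pure functions of (config, seed).
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, the main tables are
#'   written as TSV and the manifest as JSON.
#' @return A `pipeline_result` list: `microstates`, `microstate_match`,
#'   `erp_components`, `erp_anova`, `metrics`, `behavior`, `valence`,
#'   `stat_tests`, `correlations`, `topography`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(name) {
    now <- proc.time()[["elapsed"]]
    stage_times[[name]] <<- now - t0
    t0 <<- now
  }
  scfg <- config$synth
  n_sub <- scfg$n_subjects
  conds <- scfg$condition_labels

  # --- synthesis + preprocessing + per-block connectivity/network ---------
  pp <- config$preprocess
  sum_erp <- NULL     # running sum of condition x channel x time grand average
  n_trials_cond <- setNames(numeric(length(conds)), conds)
  adjacency <- list()
  keys <- list()
  epochs_last <- NULL
  truth_coupling <- list()
  for (s in seq_len(n_sub)) {
    gen <- generate_recording(scfg, seed = seed + s)
    truth_coupling[[s]] <- dplyr::mutate(gen$truth$coupling, subject = s)
    epochs <- preprocess(gen$recording, gen$events,
                         target_fs = pp$target_fs, lo = pp$lo, hi = pp$hi,
                         tmin = pp$tmin, tmax = pp$tmax,
                         peak_to_peak_max = pp$peak_to_peak_max,
                         filter_method = pp$filter_method)
    n_t <- dim(epochs$data)[3]
    if (is.null(sum_erp)) {
      sum_erp <- array(0, dim = c(length(conds), length(epochs$labels), n_t),
                       dimnames = list(conds, epochs$labels, NULL))
    }
    for (cond in conds) {
      sel <- epochs$kept & epochs$condition == cond
      if (any(sel)) {
        sum_erp[cond, , ] <- sum_erp[cond, , ] +
          colSums(epochs$data[sel, , , drop = FALSE], dims = 1)
        n_trials_cond[cond] <- n_trials_cond[cond] + sum(sel)
      }
    }
    for (b in seq_len(scfg$n_blocks)) {
      cond <- conds[b]
      sel <- epochs$kept & epochs$condition == cond
      block_ep <- eeg_epochs(epochs$data[sel, , , drop = FALSE], epochs$fs,
                             epochs$tmin, epochs$tmax,
                             epochs$condition[sel], epochs$labels,
                             epochs$positions)
      adjacency[[length(adjacency) + 1]] <- connectivity_adjacency(
        block_ep, bands = config$connectivity$bands,
        seg_len_s = config$connectivity$seg_len_s)
      keys[[length(keys) + 1]] <- tibble::tibble(subject = s, block = b,
                                                 condition = cond)
    }
    epochs_last <- epochs
  }
  keys <- dplyr::bind_rows(keys)
  grand <- sum_erp
  for (cond in conds) grand[cond, , ] <- grand[cond, , ] / n_trials_cond[cond]
  tick("synthesis_preprocess_connectivity")

  # --- microstates on the per-condition grand-average ERP -----------------
  ms <- lapply(conds, function(cond) {
    microstate_analysis(grand[cond, , ], fs = epochs_last$fs,
                        k_min = config$microstate$k_min,
                        k_max = config$microstate$k_max,
                        polarity = config$microstate$polarity,
                        min_separation_ms = config$microstate$min_separation_ms,
                        channel_labels = epochs_last$labels)
  })
  names(ms) <- conds
  ms_match <- match_across_conditions(lapply(ms, function(m) m$solution))
  tick("microstate")

  # --- ERP components + pointwise ANOVA -----------------------------------
  comp <- erp_component_table(
    epochs_from_grand(grand, epochs_last), electrodes = config$erp$electrodes,
    component = config$erp$component)
  anova_res <- pointwise_anova(epochs_last, config$erp$electrodes[1],
                               alpha = config$erp$alpha,
                               min_run_ms = config$erp$min_run_ms)
  tick("erp")

  # --- graph metrics -------------------------------------------------------
  metrics <- summarize_graph_metrics(adjacency, keys = keys)
  tick("network")

  # --- behavior, valence, statistics layer --------------------------------
  band <- config$stats$metric_band
  mband <- dplyr::filter(metrics, .data$band == !!band)
  metric_vals <- vapply(seq_len(nrow(mband)), function(i) {
    designated_metric(mband[i, ], config$stats, epochs_last$labels)
  }, numeric(1))
  behavior <- generate_behavior(scfg, metric_vals,
                                conditions = mband$condition,
                                seed = seed + 10000L)
  behavior$subject <- mband$subject
  behavior$block <- mband$block
  valence <- generate_valence(scfg, seed = seed + 20000L)

  stat_tests <- list()
  for (cond in setdiff(conds, "None")) {
    v <- dplyr::filter(valence, .data$condition == cond)
    stat_tests[[length(stat_tests) + 1]] <-
      dplyr::mutate(paired_ttest(v$pre, v$post), target = paste0("valence_", cond))
  }
  acc_groups <- split(behavior$correct, behavior$condition)
  rt_groups <- split(behavior$rt_ms, behavior$condition)
  stat_tests[[length(stat_tests) + 1]] <-
    dplyr::mutate(oneway_anova(acc_groups), target = "accuracy")
  stat_tests[[length(stat_tests) + 1]] <-
    dplyr::mutate(oneway_anova(rt_groups), target = "reaction_time")

  groups <- split_by_accuracy(behavior, k = config$stats$split_k)
  g1_blocks <- paste(groups$group1$subject, groups$group1$block)
  g2_blocks <- paste(groups$group2$subject, groups$group2$block)
  correlations <- list()
  for (b in unique(metrics$band)) {
    mb <- dplyr::filter(metrics, .data$band == !!b)
    acc <- behavior$correct[match(paste(mb$subject, mb$block),
                                  paste(behavior$subject, behavior$block))]
    for (gm in c("ge", "cpl")) {
      ok <- is.finite(mb[[gm]])
      if (sum(ok) >= 3) {
        correlations[[length(correlations) + 1]] <-
          dplyr::mutate(pearson(mb[[gm]][ok], acc[ok]), band = b, metric = gm)
      }
    }
    for (lm in c("cc_mean", "le_mean")) {
      in1 <- paste(mb$subject, mb$block) %in% g1_blocks
      in2 <- paste(mb$subject, mb$block) %in% g2_blocks
      stat_tests[[length(stat_tests) + 1]] <- dplyr::mutate(
        independent_ttest(mb[[lm]][in1], mb[[lm]][in2]),
        target = paste0(lm, "_", b, "_group1_vs_group2"))
      correlations[[length(correlations) + 1]] <-
        dplyr::mutate(pearson(mb[[lm]], acc), band = b, metric = lm)
    }
  }
  # designated midline metric correlation in the designated band
  acc_band <- behavior$correct
  correlations[[length(correlations) + 1]] <- dplyr::mutate(
    pearson(metric_vals, acc_band), band = band,
    metric = paste0("midline_", config$stats$metric))
  correlations <- dplyr::bind_rows(correlations)
  stat_tests <- dplyr::bind_rows(stat_tests)

  topo_in <- dplyr::bind_rows(lapply(seq_len(nrow(mband)), function(i) {
    grp <- if (paste(mband$subject[i], mband$block[i]) %in% g1_blocks) {
      "group1"
    } else if (paste(mband$subject[i], mband$block[i]) %in% g2_blocks) {
      "group2"
    } else {
      NA_character_
    }
    if (is.na(grp)) return(NULL)
    cc <- mband$cc[[i]]
    tibble::tibble(group = grp, electrode = names(cc), value = cc)
  }))
  topography <- topographic_summary(topo_in)
  tick("stats")

  manifest <- list(
    seed = seed,
    n_subjects = n_sub,
    n_blocks_total = nrow(keys),
    bands = config$connectivity$bands,
    designated_metric = paste0(band, " ", config$stats$metric,
                               if (isTRUE(config$stats$midline_metric)) " (midline)" else ""),
    stage_elapsed_s = as.list(stage_times),
    outputs = c("microstates", "microstate_match", "erp_components",
                "erp_anova", "metrics", "behavior", "valence",
                "stat_tests", "correlations", "topography")
  )
  result <- structure(
    list(microstates = ms, microstate_match = ms_match,
         erp_components = comp, erp_anova = anova_res,
         metrics = metrics, behavior = behavior, valence = valence,
         stat_tests = stat_tests, correlations = correlations,
         topography = topography,
         truth = list(coupling = dplyr::bind_rows(truth_coupling)),
         manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Wrap the grand-average array as single-trial epochs so the ERP table
# functions can consume it.
epochs_from_grand <- function(grand, epochs_like) {
  conds <- dimnames(grand)[[1]]
  data <- array(0, dim = c(length(conds), dim(grand)[2], dim(grand)[3]))
  for (i in seq_along(conds)) data[i, , ] <- grand[i, , ]
  eeg_epochs(data, epochs_like$fs, epochs_like$tmin, epochs_like$tmax,
             conds, epochs_like$labels, epochs_like$positions)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, %d block-band metric rows, seed %d\n",
              x$manifest$n_subjects, nrow(x$metrics), x$manifest$seed))
  cat("Stages:", paste(names(x$manifest$stage_elapsed_s), collapse = " -> "), "\n")
  invisible(x)
}

#' Write the pipeline's main tables and manifest
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(result$behavior, file.path(out_dir, "behavior.tsv"))
  write_tsv_table(result$valence, file.path(out_dir, "valence.tsv"))
  write_tsv_table(dplyr::select(result$metrics, -"cc", -"le"),
                  file.path(out_dir, "metrics.tsv"))
  write_tsv_table(result$stat_tests, file.path(out_dir, "stat_tests.tsv"))
  write_tsv_table(result$correlations, file.path(out_dir, "correlations.tsv"))
  write_tsv_table(result$erp_components, file.path(out_dir, "erp_components.tsv"))
  write_tsv_table(result$topography, file.path(out_dir, "topography.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Scaled-down validation cohort configuration
#'
#' The configuration used by the package's validation studies (tests and the
#' reproduction script): the full 16-subject, four-block design with the
#' study's sampling rate, band edges and epoch window, but a 19-channel
#' montage, 10 trials per block, 4 s simulated trials (the analyses use
#' only the 0-3.5 s decision window) and theta-band connectivity only, so
#' that a complete cohort run takes seconds rather than minutes. All
#' planted effects (P2 ordering, valence shifts, coupling direction, the
#' accuracy-metric correlation of -0.6) are the generator defaults.
#'
#' @param n_subjects Cohort size (default 16).
#' @param trials_per_block Trials per block (default 10).
#' @param bands Connectivity bands (default `"theta"`).
#' @return A [pipeline_config()].
#' @export
validation_cohort_config <- function(n_subjects = 16, trials_per_block = 10,
                                     bands = "theta") {
  pipeline_config(
    synth = synth_config(channel_labels = montage_channels(19),
                         trials_per_block = trials_per_block,
                         trial_dur = 4,
                         n_subjects = n_subjects, noise_scale = 8),
    microstate = list(k_max = 6, min_separation_ms = 20),
    connectivity = list(bands = bands),
    stats = list(split_k = 16)
  )
}
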