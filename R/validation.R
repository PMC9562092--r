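#' Validation studies
#'
#' Seeded simulation studies that exercise the package's core claims on data
#' with planted ground truth: directed-lag recovery by the phase slope
#' index, template recovery and model selection by the microstate
#' clustering, planted P2 recovery by the ERP layer, type-I calibration of
#' the statistics layer, and end-to-end recovery of a planted
#' accuracy-metric correlation by the full pipeline. The reproduction
#' script and the test suite both run these.
#'
#' @name validation-studies
NULL

#' PSI direction-recovery study
#'
#' For each seed, a two-channel system `y(t) = x(t - lag) + noise` at the
#' given SNR is simulated and the PSI from x to y is computed per band; the
#' planted direction is recovered when the index is positive.
#'
#' @param n_seeds Number of simulated systems.
#' @param lag Planted delay, samples.
#' @param snr Signal-to-noise ratio of the delayed copy.
#' @param fs Sampling rate, Hz.
#' @param n_samples Length of each simulation.
#' @param bands Band names.
#' @param seed Base RNG seed.
#' @return Tibble: seed, band, psi_xy, recovered.
#' @export
psi_direction_study <- function(n_seeds = 100, lag = 5, snr = 1, fs = 250,
                                n_samples = 30000,
                                bands = names(eeg_bands()), seed = 1L) {
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    x <- stats::rnorm(n_samples)
    y <- c(rep(0, lag), x[seq_len(n_samples - lag)]) +
      stats::rnorm(n_samples, sd = 1 / sqrt(snr))
    K <- coherency(cross_spectra(rbind(x = x, y = y), fs = fs))
    rows[[s]] <- dplyr::bind_rows(lapply(bands, function(b) {
      v <- psi(K, b)$psi[1, 2]
      tibble::tibble(seed = s, band = b, psi_xy = v, recovered = v > 0)
    }))
  }
  dplyr::bind_rows(rows)
}

#' Microstate template-recovery and model-selection study
#'
#' Per seed: 60 maps are drawn as randomly scaled copies of 3 orthogonal
#' zero-mean templates plus spatial noise at 10% of signal amplitude; the
#' clustering is scanned over K = 2..8. Reported per seed: the worst
#' absolute spatial correlation between recovered and planted templates at
#' K = 3, and the CV-selected K.
#'
#' @param n_seeds Number of repetitions.
#' @param n_channels Channel count (default 32).
#' @param n_maps Maps per repetition.
#' @param noise_frac Noise SD as a fraction of unit template amplitude.
#' @param seed Base RNG seed.
#' @return Tibble: seed, min_template_corr, k_selected.
#' @export
microstate_recovery_study <- function(n_seeds = 20, n_channels = 32,
                                      n_maps = 60, noise_frac = 0.1,
                                      seed = 1L) {
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    M <- matrix(stats::rnorm(n_channels * 3), n_channels, 3)
    M <- sweep(M, 2, colMeans(M))
    tpl <- t(qr.Q(qr(M)))                      # 3 orthonormal zero-mean maps
    lab <- rep_len(1:3, n_maps)
    amp <- stats::runif(n_maps, 0.5, 2)
    maps <- tpl[lab, , drop = FALSE] * amp +
      matrix(stats::rnorm(n_maps * n_channels,
                          sd = noise_frac / sqrt(n_channels)),
             n_maps, n_channels)
    sols <- taahc(maps, k_min = 2, k_max = 8)
    co <- abs(spatial_correlation(sols[["K=3"]]$templates, tpl))
    rows[[s]] <- tibble::tibble(
      seed = s,
      min_template_corr = min(apply(co, 2, max)),
      k_selected = select_k(sols)
    )
  }
  dplyr::bind_rows(rows)
}

#' ERP planted-effect recovery study
#'
#' Per seed: four conditions with planted frontal P2 amplitudes spaced
#' 3 uV apart (at 180 ms) and unit trial noise, 40 trials each. Recovery
#' means the measured P2 amplitudes reproduce the planted ordering and the
#' pointwise ANOVA marks an interval overlapping the planted window.
#'
#' @param n_seeds Number of repetitions.
#' @param amplitudes Named planted amplitudes, uV.
#' @param n_trials Trials per condition.
#' @param seed Base RNG seed.
#' @return Tibble: seed, order_ok, interval_ok.
#' @export
erp_recovery_study <- function(n_seeds = 20,
                               amplitudes = c(a = 2, b = 5, c = 8, d = 11),
                               n_trials = 40, seed = 1L) {
  fs <- 250
  labels <- c("FP1", "FPz", "FP2", "AF3", "AF4", "Fz", "Cz", "Pz")
  n_samp <- fs                              # 1 s epochs
  t_ms <- (seq_len(n_samp) - 1) / fs * 1000
  bump <- exp(-((t_ms - 180) / 25)^2 / 2)
  topo <- c(1, 1, 1, 1, 1, 0.3, 0, 0)
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    conds <- names(amplitudes)
    data <- array(0, dim = c(n_trials * length(conds), length(labels), n_samp))
    cond_vec <- rep(conds, each = n_trials)
    for (i in seq_len(dim(data)[1])) {
      sig <- outer(topo, bump * amplitudes[[cond_vec[i]]])
      data[i, , ] <- sig + matrix(stats::rnorm(length(labels) * n_samp),
                                  length(labels), n_samp)
    }
    ep <- eeg_epochs(data, fs, 0, 1, cond_vec, labels)
    meas <- vapply(conds, function(cond) {
      measure_component(average_epochs(ep, cond, "FPz"), "P2")$amplitude
    }, numeric(1))
    anv <- pointwise_anova(ep, "FPz", alpha = 0.05, min_run_ms = 20)
    rows[[s]] <- tibble::tibble(
      seed = s,
      order_ok = identical(order(meas), order(amplitudes)),
      interval_ok = nrow(anv$intervals) > 0 &&
        any(anv$intervals$start_ms <= 230 & anv$intervals$end_ms >= 130)
    )
  }
  dplyr::bind_rows(rows)
}

#' Type-I calibration of the statistics layer
#'
#' Null simulations for the paired t-test (n = 16), Welch t-test (16/16),
#' one-way ANOVA (4 x 16) and Pearson correlation (n = 64): all data
#' standard normal with no effect; reported is the fraction of replicates
#' with p <= alpha.
#'
#' @param n_reps Replicates per test.
#' @param alpha Nominal level.
#' @param seed Base RNG seed.
#' @return Tibble: test, rate, n_reps.
#' @export
calibration_study <- function(n_reps = 2000, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  rej <- matrix(FALSE, n_reps, 4)
  for (r in seq_len(n_reps)) {
    rej[r, 1] <- paired_ttest(stats::rnorm(16), stats::rnorm(16))$p <= alpha
    rej[r, 2] <- independent_ttest(stats::rnorm(16), stats::rnorm(16))$p <= alpha
    rej[r, 3] <- oneway_anova(lapply(1:4, function(i) stats::rnorm(16)))$p <= alpha
    rej[r, 4] <- pearson(stats::rnorm(64), stats::rnorm(64))$p <= alpha
  }
  tibble::tibble(
    test = c("paired_t", "welch_t", "oneway_anova", "pearson"),
    rate = colMeans(rej),
    n_reps = n_reps
  )
}

#' End-to-end planted-correlation recovery study
#'
#' Runs the full pipeline on the validation cohort (16 subjects, four
#' blocks, planted accuracy-metric correlation -0.6 against the midline
#' theta clustering coefficient) for `n_runs` seeds and records the Pearson
#' correlation between decision accuracy and that metric from each run.
#'
#' @param n_runs Number of pipeline runs.
#' @param config Cohort configuration (default [validation_cohort_config()]).
#' @param seed Base RNG seed.
#' @return Tibble: run, r, p, recovered (negative r with p <= 0.05).
#' @export
endtoend_recovery_study <- function(n_runs = 50,
                                    config = validation_cohort_config(),
                                    seed = 1L) {
  rows <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    res <- run_pipeline(config, seed = seed + 1000L * k)
    row <- dplyr::filter(res$correlations,
                         grepl("^midline_", .data$metric))
    rows[[k]] <- tibble::tibble(run = k, r = row$r, p = row$p,
                                recovered = row$r < 0 & row$p <= 0.05)
  }
  dplyr::bind_rows(rows)
}
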