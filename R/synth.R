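#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic EEG generator. Defaults emulate the blocked
#' decision experiment the package analyzes: 250 Hz sampling, four blocks
#' (no-stimulus `None` plus positive `H` and negative `Q`, `T` emotional
#' conditions), 40 trials per block of 6.5 s each, condition-dependent
#' frontal P2 amplitude/latency, a fronto-central P3, a late frontal
#' negativity after the second-picture onset (3 s), 1/f background noise and
#' lagged midline coupling with a known direction.
#'
#' @param channel_labels Channel set; must contain FP1, FPz, FP2, AF3, AF4
#'   and the midline electrodes Fz, Cz, Pz. Default: 32-channel 10-20 set.
#' @param fs Sampling rate, Hz.
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param trial_dur Trial duration, seconds.
#' @param condition_labels One condition label per block.
#' @param p2_amplitudes,p2_latency Named (per condition) P2 peak amplitude
#'   (uV) and latency (ms). Defaults encode the planted ordering
#'   H > None > T > Q in amplitude and a delayed P2 under fear (Q).
#' @param p3_amplitude,p3_latency,n3_amplitude,n3_latency Scalar amplitude
#'   (uV) and latency (ms) of the planted P3 and post-second-picture
#'   negativity.
#' @param coupling_spec Tibble with columns `source`, `target`, `lag`
#'   (samples, >= 1) and `gain`: additive delayed copies planted so the
#'   source leads the target.
#' @param coupling_gain_jitter SD of a per-block lognormal multiplier on all
#'   coupling gains, so planted connectivity varies across blocks.
#' @param noise_exponent Spectral slope of the 1/f background (power ~
#'   f^-exponent).
#' @param noise_scale Background RMS per channel, uV.
#' @param accuracy_metric_corr Target correlation between per-block decision
#'   accuracy and a designated graph metric (used by [generate_behavior()]).
#' @param accuracy_mean,accuracy_sd Mean/SD of correct counts, stated for a
#'   40-trial block (rescaled proportionally for other block lengths).
#' @param rt_mean Named per-condition mean reaction time, ms.
#' @param rt_sd Reaction-time SD, ms.
#' @param valence_shift Named per-condition planted shift of post- vs
#'   pre-stimulus valence on the 1-9 scale.
#' @param n_subjects Cohort size.
#' @param seed Default RNG seed for the generator functions.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(channel_labels = montage_channels(32),
                         fs = 250,
                         n_blocks = 4,
                         trials_per_block = 40,
                         trial_dur = 6.5,
                         condition_labels = c("None", "H", "Q", "T"),
                         p2_amplitudes = c(None = 4, H = 6, Q = 2.5, T = 3),
                         p2_latency = c(None = 180, H = 175, Q = 205, T = 185),
                         p3_amplitude = 3,
                         p3_latency = 350,
                         n3_amplitude = -3,
                         n3_latency = 3350,
                         coupling_spec = default_coupling(),
                         coupling_gain_jitter = 0.5,
                         noise_exponent = 1,
                         noise_scale = 10,
                         accuracy_metric_corr = -0.6,
                         accuracy_mean = 33,
                         accuracy_sd = 4,
                         rt_mean = c(None = 496, H = 472, Q = 446, T = 460),
                         rt_sd = 147,
                         valence_shift = c(None = 0, H = 3, Q = -3, T = -2.5),
                         n_subjects = 16,
                         seed = 1L) {
  required <- c("FP1", "FPz", "FP2", "AF3", "AF4", "Fz", "Cz", "Pz")
  missing <- setdiff(required, channel_labels)
  if (length(missing) > 0) {
    rlang::abort(paste0("channel_labels must include: ", paste(missing, collapse = ", ")))
  }
  if (fs <= 0) rlang::abort("fs must be positive.")
  if (length(condition_labels) != n_blocks) {
    rlang::abort("One condition label per block is required.")
  }
  if (nrow(coupling_spec) > 0) {
    if (any(coupling_spec$lag < 1)) rlang::abort("Coupling lags must be >= 1 sample.")
    bad <- setdiff(c(coupling_spec$source, coupling_spec$target), channel_labels)
    if (length(bad) > 0) {
      rlang::abort(paste0("Coupling channels not in channel_labels: ",
                          paste(unique(bad), collapse = ", ")))
    }
  }
  for (nm in c("p2_amplitudes", "p2_latency", "rt_mean", "valence_shift")) {
    v <- get(nm)
    if (!all(condition_labels %in% names(v))) {
      rlang::abort(paste0("`", nm, "` must be named for every condition."))
    }
  }
  if (abs(accuracy_metric_corr) >= 1) {
    rlang::abort("accuracy_metric_corr must lie strictly inside (-1, 1).")
  }
  cfg <- list(
    channel_labels = channel_labels, fs = fs, n_blocks = n_blocks,
    trials_per_block = trials_per_block, trial_dur = trial_dur,
    condition_labels = condition_labels,
    p2_amplitudes = p2_amplitudes, p2_latency = p2_latency,
    p3_amplitude = p3_amplitude, p3_latency = p3_latency,
    n3_amplitude = n3_amplitude, n3_latency = n3_latency,
    coupling_spec = coupling_spec, coupling_gain_jitter = coupling_gain_jitter,
    noise_exponent = noise_exponent, noise_scale = noise_scale,
    accuracy_metric_corr = accuracy_metric_corr,
    accuracy_mean = accuracy_mean, accuracy_sd = accuracy_sd,
    rt_mean = rt_mean, rt_sd = rt_sd, valence_shift = valence_shift,
    n_subjects = n_subjects, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Default planted coupling: a lagged midline chain
#'
#' Fz leads Cz, Cz leads Pz, Fz leads Pz (closing a triangle among the
#' midline electrodes), all with positive gain, so the phase-slope index and
#' the clustering coefficient of the midline have a known ground truth.
#' @return Tibble with columns `source`, `target`, `lag`, `gain`.
#' @export
default_coupling <- function() {
  tibble::tibble(
    source = c("Fz", "Cz", "Fz"),
    target = c("Cz", "Pz", "Pz"),
    lag    = c(5L, 5L, 10L),
    gain   = c(0.8, 0.8, 0.6)
  )
}

# Gaussian-windowed half-sine bump, peak-normalized, compact support.
component_bump <- function(n_samples, fs, latency_ms, width_ms, amplitude) {
  out <- numeric(n_samples)
  if (amplitude == 0) return(out)
  half <- round(width_ms / 2 / 1000 * fs)
  centre <- round(latency_ms / 1000 * fs) + 1L
  idx <- (centre - half):(centre + half)
  ok <- idx >= 1 & idx <= n_samples
  tau <- seq(0, 1, length.out = length(idx))
  shape <- sin(pi * tau) * exp(-((tau - 0.5) / 0.22)^2 / 2)
  shape <- shape / max(shape)
  out[idx[ok]] <- amplitude * shape[ok]
  out
}

# Scalp weighting of the planted components.
component_topography <- function(labels, which = c("frontal", "frontocentral")) {
  which <- match.arg(which)
  w <- setNames(numeric(length(labels)), labels)
  if (which == "frontal") {
    w[labels %in% c("FP1", "FPz", "FP2", "AF3", "AF4", "AF7", "AFz", "AF8")] <- 1
    w[labels %in% c("F7", "F3", "Fz", "F4", "F8")] <- 0.5
  } else {
    w[labels %in% c("Fz", "FCz", "Cz")] <- 1
    w[labels %in% c("F3", "F4", "FC3", "FC4", "C3", "C4")] <- 0.6
    w[labels %in% c("FP1", "FPz", "FP2", "AF3", "AF4")] <- 0.3
  }
  w
}

#' Planted ERP template for one condition
#'
#' Channels x samples matrix over one trial: a frontal P2 with
#' condition-dependent amplitude and latency, a fronto-central P3, and a
#' frontal negativity after the second-picture onset. Zero outside the
#' component windows.
#'
#' @param config A [synth_config()].
#' @param condition Condition label.
#' @return Numeric matrix, channels x trial samples.
#' @export
erp_template <- function(config, condition) {
  n <- round(config$trial_dur * config$fs)
  lab <- config$channel_labels
  frontal <- component_topography(lab, "frontal")
  fcentral <- component_topography(lab, "frontocentral")
  p2 <- component_bump(n, config$fs, config$p2_latency[[condition]], 100,
                       config$p2_amplitudes[[condition]])
  p3 <- component_bump(n, config$fs, config$p3_latency, 150, config$p3_amplitude)
  n3 <- component_bump(n, config$fs, config$n3_latency, 120, config$n3_amplitude)
  outer(frontal, p2) + outer(fcentral, p3) + outer(frontal, n3)
}

# Spectrally shaped Gaussian noise: white noise FFT-filtered to power ~
# f^-exponent over >= 1 Hz (flat below 1 Hz to avoid the DC singularity).
shaped_noise <- function(n, fs, exponent, scale) {
  if (scale == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent == 0) return(scale * w)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  amp <- pmax(f_fold, 1)^(-exponent / 2)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  scale * x / stats::sd(x)
}

# Multichannel variant synthesized directly in the frequency domain (the
# forward transform of white noise is complex Gaussian, so drawing the
# spectrum directly and inverting once per batch is equivalent and cheaper).
shaped_noise_matrix <- function(n, n_ch, fs, exponent, scale) {
  out <- matrix(0, n_ch, n)
  if (scale == 0) return(out)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  amp <- pmax(f_fold, 1)^(-exponent / 2)
  half <- floor((n - 1) / 2)        # strictly positive, non-Nyquist bins
  Z <- matrix(0 + 0i, n, n_ch)
  Z[1, ] <- stats::rnorm(n_ch)
  re <- matrix(stats::rnorm(half * n_ch), half, n_ch)
  im <- matrix(stats::rnorm(half * n_ch), half, n_ch)
  Z[2:(half + 1), ] <- (re + 1i * im) / sqrt(2)
  Z[n:(n - half + 1), ] <- Conj(Z[2:(half + 1), ])
  if (n %% 2 == 0) Z[n / 2 + 1, ] <- stats::rnorm(n_ch)
  x <- Re(stats::mvfft(Z * amp, inverse = TRUE))
  for (ch in seq_len(n_ch)) out[ch, ] <- scale * x[, ch] / stats::sd(x[, ch])
  out
}

#' Generate a synthetic continuous recording with planted ground truth
#'
#' Builds one continuous multi-block recording: per-channel 1/f-shaped
#' Gaussian background, the condition-specific ERP template inserted at each
#' trial onset, and additive delayed copies per `coupling_spec` (scaled by a
#' per-block lognormal gain multiplier). Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed; defaults to `config$seed`. `NULL` uses the current
#'   RNG state.
#' @return A list with elements `recording` ([eeg_recording]), `events`
#'   (tibble: block, trial, onset_s, condition) and `truth` (list:
#'   `erp_templates` condition x channel x sample array, `coupling` tibble
#'   with per-block gain multipliers, `planted_valence_shift`).
#' @export
generate_recording <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fs
  lab <- config$channel_labels
  n_ch <- length(lab)
  trial_n <- round(config$trial_dur * fs)
  block_n <- config$trials_per_block * trial_n
  total_n <- config$n_blocks * block_n

  data <- shaped_noise_matrix(total_n, n_ch, fs, config$noise_exponent,
                              config$noise_scale)
  dimnames(data) <- list(lab, NULL)

  templates <- array(
    0, dim = c(config$n_blocks, n_ch, trial_n),
    dimnames = list(config$condition_labels, lab, NULL)
  )
  events <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    cond <- config$condition_labels[b]
    tpl <- erp_template(config, cond)
    templates[b, , ] <- tpl
    onsets <- (b - 1L) * block_n + (seq_len(config$trials_per_block) - 1L) * trial_n
    for (o in onsets) {
      data[, (o + 1):(o + trial_n)] <- data[, (o + 1):(o + trial_n)] + tpl
    }
    events[[b]] <- tibble::tibble(
      block = b, trial = seq_len(config$trials_per_block),
      onset_s = onsets / fs, condition = cond
    )
  }
  events <- dplyr::bind_rows(events)

  block_gain <- rep(1, config$n_blocks)
  if (nrow(config$coupling_spec) > 0) {
    if (config$coupling_gain_jitter > 0) {
      block_gain <- exp(stats::rnorm(config$n_blocks, 0, config$coupling_gain_jitter))
    }
    base <- data  # pre-coupling copy: sources are the uncoupled signals
    for (b in seq_len(config$n_blocks)) {
      rng <- ((b - 1L) * block_n + 1L):(b * block_n)
      for (k in seq_len(nrow(config$coupling_spec))) {
        src <- config$coupling_spec$source[k]
        tgt <- config$coupling_spec$target[k]
        lag <- config$coupling_spec$lag[k]
        g <- config$coupling_spec$gain[k] * block_gain[b]
        seg <- base[src, rng]
        shifted <- c(rep(0, lag), seg[seq_len(length(seg) - lag)])
        data[tgt, rng] <- data[tgt, rng] + g * shifted
      }
    }
  }

  truth <- list(
    erp_templates = templates,
    coupling = dplyr::mutate(
      tidyr::crossing(block = seq_len(config$n_blocks), config$coupling_spec),
      gain_multiplier = block_gain[.data$block]
    ),
    planted_valence_shift = config$valence_shift
  )
  list(
    recording = eeg_recording(data, fs, lab, reference = "raw"),
    events = events,
    truth = truth
  )
}

#' Generate per-block behavioral data tied to a graph metric
#'
#' Correct counts are drawn so that their sample correlation with
#' `metric_values` approaches `config$accuracy_metric_corr` as the number of
#' blocks grows: a standardized copy of the metric is mixed with independent
#' Gaussian noise at the target correlation, rescaled to the configured
#' accuracy mean/SD, rounded and clipped to \[0, 40\].
#'
#' @param config A [synth_config()].
#' @param metric_values One designated graph-metric value per block.
#' @param conditions Optional per-block condition labels (used for the
#'   reaction-time means); recycled from the config if omitted.
#' @param seed RNG seed (`NULL`: current state).
#' @return Tibble: `block`, `condition`, `correct` (0-40), `rt_ms`.
#' @export
generate_behavior <- function(config, metric_values, conditions = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rho <- config$accuracy_metric_corr
  if (abs(rho) >= 1) rlang::abort("accuracy_metric_corr must be in (-1, 1).")
  n <- length(metric_values)
  if (n == 0) {
    return(tibble::tibble(block = integer(), condition = character(),
                          correct = integer(), rt_ms = numeric()))
  }
  conditions <- conditions %||%
    rep_len(config$condition_labels, n)
  zm <- if (stats::sd(metric_values) > 0) {
    as.numeric(scale(metric_values))
  } else {
    numeric(n)
  }
  z <- rho * zm + sqrt(1 - rho^2) * stats::rnorm(n)
  # accuracy_mean/accuracy_sd are stated for a 40-trial block; rescale to
  # the configured block length so shorter simulated blocks keep the same
  # relative accuracy distribution
  max_trials <- config$trials_per_block
  mu <- config$accuracy_mean * max_trials / 40
  sig <- config$accuracy_sd * max_trials / 40
  correct <- as.integer(pmin(max_trials, pmax(0, round(mu + sig * z))))
  rt <- stats::rnorm(n, mean = config$rt_mean[conditions], sd = config$rt_sd)
  rt <- pmax(rt, 150)
  tibble::tibble(block = seq_len(n), condition = conditions,
                 correct = correct, rt_ms = rt)
}

#' Generate pre/post valence self-reports
#'
#' Per-subject, per-condition valence on the 1-9 scale: pre-stimulus scores
#' around the neutral midpoint, post-stimulus scores shifted by the planted
#' per-condition shift plus unit noise, both rounded and clipped to \[1, 9\].
#'
#' @param config A [synth_config()].
#' @param n_subjects Cohort size (default from config).
#' @param seed RNG seed (`NULL`: current state).
#' @return Tibble: `subject`, `condition`, `pre`, `post`.
#' @export
generate_valence <- function(config, n_subjects = config$n_subjects,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clip19 <- function(x) pmin(9L, pmax(1L, as.integer(round(x))))
  out <- lapply(config$condition_labels, function(cond) {
    pre <- clip19(stats::rnorm(n_subjects, 5, 1))
    post <- clip19(pre + config$valence_shift[[cond]] +
                     stats::rnorm(n_subjects, 0, 1))
    tibble::tibble(subject = seq_len(n_subjects), condition = cond,
                   pre = pre, post = post)
  })
  dplyr::bind_rows(out)
}
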