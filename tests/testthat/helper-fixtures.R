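# Shared fixture builders for the test suite.

# A small, fast generator configuration: 19 channels, short blocks.
small_config <- function(...) {
  args <- utils::modifyList(
    list(channel_labels = montage_channels(19), trials_per_block = 6,
         noise_scale = 8),
    list(...))
  do.call(synth_config, args)
}

# No couplings at all.
no_coupling <- function() {
  tibble::tibble(source = character(), target = character(),
                 lag = integer(), gain = numeric())
}

# Silence the planted ERP components.
silent_components <- function() {
  list(p2_amplitudes = c(None = 0, H = 0, Q = 0, T = 0),
       p3_amplitude = 0, n3_amplitude = 0)
}

# k orthonormal, zero-mean template maps over n_ch channels.
orthogonal_templates <- function(n_ch, k, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n_ch * k), n_ch, k)
  M <- sweep(M, 2, colMeans(M))            # zero-sum subspace
  Q <- qr.Q(qr(M))                          # stays zero-mean (closed subspace)
  t(Q)                                      # k x n_ch rows
}

# Noisy scaled copies of planted templates: maps x channels plus labels.
template_maps <- function(templates, n_maps, noise_sd, seed = 1) {
  set.seed(seed)
  k <- nrow(templates)
  n_ch <- ncol(templates)
  lab <- rep_len(seq_len(k), n_maps)
  amp <- stats::runif(n_maps, 0.5, 2)
  maps <- templates[lab, , drop = FALSE] * amp +
    matrix(rnorm(n_maps * n_ch, sd = noise_sd), n_maps, n_ch)
  list(maps = maps, labels = lab)
}

# Epochs with a planted P2-like bump at one frontal electrode group,
# condition-dependent amplitude, iid unit noise elsewhere.
planted_p2_epochs <- function(amps, n_trials = 40, fs = 250, dur = 1,
                              noise_sd = 1, latency_ms = 180, seed = 1) {
  set.seed(seed)
  labels <- c("FP1", "FPz", "FP2", "AF3", "AF4", "Fz", "Cz", "Pz")
  n_samp <- round(dur * fs)
  t_ms <- (seq_len(n_samp) - 1) / fs * 1000
  bump <- exp(-((t_ms - latency_ms) / 25)^2 / 2)
  conds <- names(amps)
  data <- array(0, dim = c(n_trials * length(conds), length(labels), n_samp))
  cond_vec <- character(n_trials * length(conds))
  i <- 0
  for (cond in conds) {
    for (tr in seq_len(n_trials)) {
      i <- i + 1
      sig <- outer(c(1, 1, 1, 1, 1, 0.3, 0, 0), bump * amps[[cond]])
      data[i, , ] <- sig + matrix(rnorm(length(labels) * n_samp, sd = noise_sd),
                                  length(labels), n_samp)
      cond_vec[i] <- cond
    }
  }
  eeg_epochs(data, fs, 0, dur, cond_vec, labels)
}

# Two-channel delayed-copy system at a given SNR; returns channels x samples.
delayed_pair <- function(n, lag = 5, snr = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- c(rep(0, lag), x[seq_len(n - lag)]) + rnorm(n, sd = 1 / sqrt(snr))
  rbind(x = x, y = y)
}
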