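#' Resample a recording
#'
#' Polyphase antialiasing resampling (via [signal::resample()]) applied per
#' channel. Duration is preserved to within one sample. Upsampling is
#' permitted but flagged with a message.
#'
#' @param rec An [eeg_recording].
#' @param target_fs Target sampling rate, Hz.
#' @return A resampled [eeg_recording].
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs <= 0) rlang::abort("target_fs must be positive.")
  if (target_fs == rec$fs) return(rec)
  if (target_fs > rec$fs) {
    rlang::inform(sprintf("Upsampling from %g to %g Hz.", rec$fs, target_fs))
  }
  scale <- 1e6
  p <- round(target_fs * scale)
  q <- round(rec$fs * scale)
  g <- pracma_gcd(p, q)
  p <- p / g
  q <- q / g
  out <- t(apply(rec$data, 1, function(x) signal::resample(x, p, q)))
  eeg_recording(out, target_fs, rec$labels, rec$positions, rec$reference)
}

# Euclid's gcd (integers stored in doubles).
pracma_gcd <- function(a, b) {
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth high-pass and low-pass sections with zero phase,
#' so component latencies are preserved. Two numerically equivalent
#' implementations are provided: `"filtfilt"` applies the sections
#' forward-backward per channel ([signal::filtfilt()]); `"fft"` multiplies
#' each channel's spectrum by the identical squared Butterworth magnitude
#' response (what forward-backward filtering realizes in-band), which is
#' much faster on long multichannel recordings and differs only in its
#' edge handling (circular rather than padded).
#'
#' @param rec An [eeg_recording].
#' @param lo,hi Band edges, Hz (defaults 1 and 40).
#' @param method `"filtfilt"` (default) or `"fft"`.
#' @return A filtered [eeg_recording].
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 40,
                            method = c("filtfilt", "fft")) {
  method <- match.arg(method)
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi)) rlang::abort("Require 0 < lo < hi.")
  if (hi >= nyq) rlang::abort("hi must be below the Nyquist frequency.")
  if (method == "filtfilt") {
    bh <- signal::butter(4, lo / nyq, type = "high")
    bl <- signal::butter(4, hi / nyq, type = "low")
    out <- t(apply(rec$data, 1, function(x) {
      signal::filtfilt(bl, signal::filtfilt(bh, x))
    }))
  } else {
    n <- ncol(rec$data)
    f <- (seq_len(n) - 1) * rec$fs / n
    f <- pmin(f, rec$fs - f)
    # squared magnitude of the bilinear-designed digital Butterworth
    # sections (frequency axis warped as tan(pi f / fs))
    g <- tan(pi * f / rec$fs)
    g_hi <- tan(pi * hi / rec$fs)
    g_lo <- tan(pi * lo / rec$fs)
    h <- 1 / (1 + (g / g_hi)^8)
    h <- h * ifelse(g > 0, 1 / (1 + (g_lo / g)^8), 0)
    F <- stats::mvfft(t(rec$data))
    out <- t(Re(stats::mvfft(F * h, inverse = TRUE)) / n)
  }
  eeg_recording(out, rec$fs, rec$labels, rec$positions, rec$reference)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels, so every sample's
#' channel mean is zero. Idempotent.
#'
#' @param rec An [eeg_recording] (>= 2 channels).
#' @return An average-referenced [eeg_recording] (`reference = "average"`).
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2) rlang::abort("Average reference needs >= 2 channels.")
  out <- sweep(rec$data, 2, colMeans(rec$data))
  eeg_recording(out, rec$fs, rec$labels, rec$positions, reference = "average")
}

#' Cut epochs around event onsets
#'
#' Slices `[tmin, tmax)` relative to each event onset (default the 0-3.5 s
#' decision window). Events whose window extends past the end of the
#' recording are dropped with a warning.
#'
#' @param rec An [eeg_recording].
#' @param events Tibble with columns `onset_s` and `condition` (optionally
#'   `block`, `trial`).
#' @param tmin,tmax Window in seconds relative to onset (`tmin < tmax`).
#' @return An [eeg_epochs] object.
#' @export
epoch_recording <- function(rec, events, tmin = 0, tmax = 3.5) {
  if (tmin >= tmax) rlang::abort("tmin must be < tmax.")
  n_samp <- round((tmax - tmin) * rec$fs)
  starts <- round(events$onset_s * rec$fs) + round(tmin * rec$fs) + 1L
  ends <- starts + n_samp - 1L
  ok <- starts >= 1 & ends <= ncol(rec$data)
  if (any(!ok)) {
    rlang::warn(sprintf("%d event(s) beyond the recording were dropped.", sum(!ok)))
  }
  if (!any(ok)) rlang::abort("No event window fits inside the recording.")
  starts <- starts[ok]
  data <- array(0, dim = c(sum(ok), nrow(rec$data), n_samp))
  for (i in seq_along(starts)) {
    data[i, , ] <- rec$data[, starts[i]:(starts[i] + n_samp - 1L)]
  }
  eeg_epochs(data, rec$fs, tmin, tmax, events$condition[ok],
             rec$labels, rec$positions)
}

#' Reject epochs on peak-to-peak amplitude
#'
#' Marks as rejected any trial whose peak-to-peak amplitude on any channel
#' exceeds the threshold. This amplitude criterion is the package's
#' deterministic stand-in for artifact-correction stages (subspace
#' reconstruction, independent component analysis) that real recordings
#' need; the synthetic data carry no such artifacts.
#'
#' @param epochs An [eeg_epochs].
#' @param peak_to_peak_max Threshold, uV (default 200).
#' @return The [eeg_epochs] with an updated `kept` mask.
#' @export
reject_epochs <- function(epochs, peak_to_peak_max = 200) {
  if (peak_to_peak_max <= 0) rlang::abort("peak_to_peak_max must be positive.")
  p2p <- apply(epochs$data, 1, function(tr) {
    max(apply(tr, 1, function(ch) max(ch) - min(ch)))
  })
  keep <- p2p <= peak_to_peak_max
  if (!any(keep)) {
    rlang::abort("All trials exceed the peak-to-peak threshold; review the threshold.")
  }
  n_rej <- sum(!keep)
  if (n_rej > 0) {
    rlang::inform(sprintf("Rejected %d of %d trials (peak-to-peak > %g uV).",
                          n_rej, length(keep), peak_to_peak_max))
  }
  epochs$kept <- epochs$kept & keep
  epochs
}

#' Standard conditioning chain
#'
#' Convenience wrapper: optional resampling, band-pass filtering, average
#' referencing, epoching and amplitude rejection with the package defaults.
#'
#' @param rec An [eeg_recording].
#' @param events Event tibble (see [epoch_recording()]).
#' @param target_fs Resample target (skipped when equal to `rec$fs`).
#' @param lo,hi Band edges, Hz.
#' @param tmin,tmax Epoch window, s.
#' @param peak_to_peak_max Rejection threshold, uV.
#' @param filter_method Band-pass implementation (see [bandpass_filter()]).
#' @return An [eeg_epochs] object.
#' @export
preprocess <- function(rec, events, target_fs = 250, lo = 1, hi = 40,
                       tmin = 0, tmax = 3.5, peak_to_peak_max = 200,
                       filter_method = "filtfilt") {
  rec <- resample_recording(rec, target_fs)
  rec <- bandpass_filter(rec, lo, hi, method = filter_method)
  rec <- average_reference(rec)
  epochs <- epoch_recording(rec, events, tmin, tmax)
  reject_epochs(epochs, peak_to_peak_max)
}
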