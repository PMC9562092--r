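#' EEG recording container
#'
#' A continuous multichannel EEG time-series with montage metadata. Data are
#' stored as a channels x samples matrix in microvolts.
#'
#' @param data Numeric matrix, channels x samples (uV). Row names, if
#'   present, must match `labels`.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique channel names.
#' @param positions Tibble with columns `channel`, `x`, `y` covering every
#'   label (defaults to the shipped 10-20 montage).
#' @param reference Reference tag, `"raw"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = rownames(data),
                          positions = NULL, reference = "raw") {
  data <- as.matrix(data)
  if (is.null(labels)) {
    labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (anyDuplicated(labels)) rlang::abort("Channel labels must be unique.")
  if (length(labels) != nrow(data)) {
    rlang::abort("`labels` length must equal the number of data rows.")
  }
  if (anyNA(data)) rlang::abort("Recording data must not contain NA.")
  if (!is.numeric(fs) || fs <= 0) rlang::abort("`fs` must be positive.")
  if (is.null(positions)) {
    positions <- tryCatch(ten_twenty_montage(labels), error = function(e) NULL)
  }
  if (!is.null(positions) && !all(labels %in% positions$channel)) {
    rlang::abort("`positions` must cover every channel label.")
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         positions = positions, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  invisible(x)
}

#' Epoched EEG container
#'
#' Trials x channels x samples array cut around event onsets, with per-trial
#' condition labels and a kept/rejected mask.
#'
#' @param data 3-D numeric array, trials x channels x samples.
#' @param fs Sampling rate (Hz).
#' @param tmin,tmax Epoch window in seconds relative to event onset.
#' @param condition Character vector, one label per trial.
#' @param labels Channel labels.
#' @param positions Montage tibble (may be `NULL`).
#' @param kept Logical per-trial mask (defaults to all `TRUE`).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, tmin, tmax, condition, labels,
                       positions = NULL, kept = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_expected <- round((tmax - tmin) * fs)
  if (dim(data)[3] != n_expected) {
    rlang::abort(sprintf("Epoch sample count %d != round((tmax - tmin) * fs) = %d.",
                         dim(data)[3], n_expected))
  }
  if (length(condition) != dim(data)[1]) {
    rlang::abort("One condition label per trial is required.")
  }
  kept <- kept %||% rep(TRUE, dim(data)[1])
  structure(
    list(data = data, fs = fs, tmin = tmin, tmax = tmax,
         condition = as.character(condition), labels = labels,
         positions = positions, kept = kept),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials (%d kept) x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
              d[1], sum(x$kept), d[2], d[3], x$fs, x$tmin, x$tmax))
  invisible(x)
}

#' Epoch time axis in milliseconds
#' @param epochs An `eeg_epochs` object.
#' @return Numeric vector of per-sample times (ms, relative to onset).
#' @export
epoch_times_ms <- function(epochs) {
  n <- dim(epochs$data)[3]
  (epochs$tmin + (seq_len(n) - 1) / epochs$fs) * 1000
}
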