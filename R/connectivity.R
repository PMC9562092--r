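#' Welch-averaged cross-spectra with 50%-overlap Hamming windows
#'
#' Hamming-tapered FFT per 50%-overlapping segment (segments are demeaned
#' per channel), averaged into the one-sided cross-spectral matrix
#' `S_ij(f) = mean over segments of X_i(f) * Conj(X_j(f))`. Epoched input is
#' pooled: each kept trial contributes its own segments, so no segment
#' spans an epoch boundary. The frequency resolution is `1 / seg_len_s`.
#'
#' @param x Channels x samples matrix, or an [eeg_epochs] object.
#' @param fs Sampling rate, Hz (taken from the epochs when omitted).
#' @param seg_len_s Segment length, seconds (default 1 s, i.e. 1 Hz
#'   resolution, so every canonical band holds several grid frequencies).
#' @return A `cross_spectrum`: list with `S` (channels x channels x
#'   frequencies complex array), `freqs` (Hz), `delta_f`, `n_segments`,
#'   `labels`.
#' @export
cross_spectra <- function(x, fs = NULL, seg_len_s = 1) {
  if (inherits(x, "eeg_epochs")) {
    fs <- fs %||% x$fs
    labels <- x$labels
    kept <- which(x$kept)
    chunks <- lapply(kept, function(i) x$data[i, , , drop = TRUE])
  } else {
    if (is.null(fs)) rlang::abort("fs is required for matrix input.")
    labels <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
    chunks <- list(as.matrix(x))
  }
  L <- round(seg_len_s * fs)
  if (L < 8) rlang::abort("Segment length must cover >= 8 samples.")
  step <- max(1L, floor(L / 2))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming
  n_f <- floor(L / 2) + 1L
  n_ch <- nrow(chunks[[1]])

  segs <- list()
  for (chunk in chunks) {
    n <- ncol(chunk)
    if (n < L) next
    starts <- seq(1L, n - L + 1L, by = step)
    for (s in starts) segs[[length(segs) + 1]] <- chunk[, s:(s + L - 1L), drop = FALSE]
  }
  if (length(segs) == 0) rlang::abort("Data shorter than one segment.")

  # FFT all segments in one batched call: columns are (channel, segment)
  n_seg <- length(segs)
  big <- matrix(0, L, n_ch * n_seg)
  for (k in seq_len(n_seg)) {
    seg <- segs[[k]] - rowMeans(segs[[k]])
    big[, ((k - 1) * n_ch + 1):(k * n_ch)] <- t(seg)
  }
  big <- big * w
  X <- array(stats::mvfft(big)[seq_len(n_f), , drop = FALSE],
             dim = c(n_f, n_ch, n_seg))
  scale <- 1 / (fs * sum(w^2) * length(segs))
  S <- array(0 + 0i, dim = c(n_ch, n_ch, n_f),
             dimnames = list(labels, labels, NULL))
  for (f in seq_len(n_f)) {
    Xf <- matrix(X[f, , ], nrow = n_ch)       # n_ch x n_seg
    Sf <- (Xf %*% Conj(t(Xf))) * scale        # S_ij = sum_seg X_i Conj(X_j)
    S[, , f] <- (Sf + Conj(t(Sf))) / 2        # enforce exact Hermitian symmetry
  }
  structure(
    list(S = S, freqs = (seq_len(n_f) - 1) * fs / L, delta_f = fs / L,
         n_segments = length(segs), labels = labels),
    class = "cross_spectrum"
  )
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d channels, %d frequencies (df = %g Hz), %d segments\n",
              dim(x$S)[1], length(x$freqs), x$delta_f, x$n_segments))
  invisible(x)
}

#' Complex coherency
#'
#' `K_ij(f) = S_ij(f) / sqrt(S_ii(f) * S_jj(f))`: magnitude is the
#' coherence, argument the cross-spectral phase. Pairs with a vanishing
#' auto-spectrum are set to zero with a warning.
#'
#' @param cs A `cross_spectrum`.
#' @return A `coherency` object: list with `K` (channels x channels x
#'   frequencies complex), `freqs`, `delta_f`, `labels`.
#' @export
coherency <- function(cs) {
  S <- cs$S
  n_f <- dim(S)[3]
  K <- S
  degenerate <- FALSE
  for (f in seq_len(n_f)) {
    d <- Re(diag(S[, , f]))
    bad <- d <= 0
    d[bad] <- 1
    K[, , f] <- S[, , f] / sqrt(outer(d, d))
    if (any(bad)) {
      K[bad, , f] <- 0
      K[, bad, f] <- 0
      degenerate <- TRUE
    }
  }
  if (degenerate) rlang::warn("Zero auto-spectrum encountered; affected pairs set to 0.")
  structure(list(K = K, freqs = cs$freqs, delta_f = cs$delta_f,
                 labels = cs$labels),
            class = "coherency")
}

#' Canonical EEG frequency bands
#' @return Named list of `(lo, hi)` band edges in Hz: delta 1-4, theta 4-8,
#'   alpha 8-13, beta 13-30, gamma 30-40.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 40))
}

#' Phase slope index for one band
#'
#' `Psi_ij = Im( sum over f in F of Conj(K_ij(f)) * K_ij(f + delta_f) )`,
#' where F is the set of grid frequencies with both `f` and `f + delta_f`
#' inside `[lo, hi)`. A positive `Psi_ij` means channel i temporally leads
#' channel j (the cross-spectral phase rises with frequency). The matrix is
#' exactly antisymmetric with zero diagonal. The index is left
#' un-normalized.
#'
#' @param K A [coherency()] result.
#' @param band Length-2 numeric `(lo, hi)` in Hz, or a band name from
#'   [eeg_bands()].
#' @return A `psi_matrix`: list with `psi` (channels x channels), `band`,
#'   `band_range`, `freqs_used`, `labels`.
#' @export
psi <- function(K, band = "theta") {
  if (is.character(band)) {
    band_name <- band
    band <- eeg_bands()[[band]]
    if (is.null(band)) rlang::abort("Unknown band name.")
  } else {
    band_name <- paste0(band[1], "-", band[2], "Hz")
  }
  df <- K$delta_f
  freqs <- K$freqs
  idx <- which(freqs >= band[1] & freqs < band[2] &
                 (freqs + df) >= band[1] & (freqs + df) < band[2])
  idx <- idx[idx + 1 <= length(freqs)]
  if (length(idx) < 1 || length(unique(c(idx, idx + 1))) < 2) {
    rlang::abort("Band holds fewer than 2 grid frequencies.")
  }
  acc <- matrix(0, dim(K$K)[1], dim(K$K)[2])
  for (i in idx) {
    acc <- acc + Im(Conj(K$K[, , i]) * K$K[, , i + 1])
  }
  dimnames(acc) <- list(K$labels, K$labels)
  structure(
    list(psi = acc, band = band_name, band_range = band,
         freqs_used = freqs[idx], labels = K$labels),
    class = "psi_matrix"
  )
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("<psi_matrix> %d channels, band %s (%d frequency pairs)\n",
              nrow(x$psi), x$band, length(x$freqs_used)))
  invisible(x)
}

#' Directed weighted adjacency from a PSI matrix
#'
#' Keeps the positive direction of each antisymmetric pair: `W_ij = Psi_ij`
#' if `Psi_ij > 0`, else 0 (an edge i -> j when i leads j). Negative entries
#' are dropped rather than reversed; by antisymmetry the two conventions
#' carry the same information.
#'
#' @param psi_mat A `psi_matrix` (or bare antisymmetric matrix).
#' @return Nonnegative directed adjacency matrix, zero diagonal.
#' @export
psi_to_adjacency <- function(psi_mat) {
  m <- if (inherits(psi_mat, "psi_matrix")) psi_mat$psi else as.matrix(psi_mat)
  W <- pmax(m, 0)
  diag(W) <- 0
  W
}

#' Band-wise PSI adjacency from epochs
#'
#' Convenience wrapper: Welch cross-spectra pooled over kept epochs,
#' coherency, PSI per requested band, positive-part adjacency.
#'
#' @param epochs An [eeg_epochs] (or channels x samples matrix with `fs`).
#' @param bands Character vector of band names (default all five).
#' @param seg_len_s Welch segment length, s.
#' @param fs Sampling rate for matrix input.
#' @return Named list of adjacency matrices, one per band, with the
#'   `psi_matrix` attached as attribute `"psi"`.
#' @export
connectivity_adjacency <- function(epochs, bands = names(eeg_bands()),
                                   seg_len_s = 1, fs = NULL) {
  cs <- cross_spectra(epochs, fs = fs, seg_len_s = seg_len_s)
  K <- coherency(cs)
  out <- lapply(bands, function(b) {
    p <- psi(K, b)
    W <- psi_to_adjacency(p)
    attr(W, "psi") <- p
    W
  })
  names(out) <- bands
  out
}
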