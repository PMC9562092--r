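#' Standard 10-20 scalp montage (2-D projected positions)
#'
#' Electrode positions from the international 10-20 system, projected onto a
#' unit disc (x: left-to-right, y: back-to-front, vertex Cz at the origin).
#' Shipped as a static table so topographic summaries need no external
#' downloads.
#'
#' @param channels Optional character vector of labels to select (in order).
#'   `NULL` returns the full table.
#' @return A tibble with columns `channel`, `x`, `y`, `midline` (logical).
#' @export
#' @examples
#' ten_twenty_montage(c("Fz", "Cz", "Pz"))
ten_twenty_montage <- function(channels = NULL) {
  pos <- tibble::tribble(
    ~channel,     ~x,     ~y,
    "FP1",     -0.28,   0.85,
    "FPz",      0.00,   0.90,
    "FP2",      0.28,   0.85,
    "AF7",     -0.53,   0.73,
    "AF3",     -0.33,   0.70,
    "AFz",      0.00,   0.72,
    "AF4",      0.33,   0.70,
    "AF8",      0.53,   0.73,
    "F7",      -0.73,   0.53,
    "F3",      -0.45,   0.47,
    "Fz",       0.00,   0.54,
    "F4",       0.45,   0.47,
    "F8",       0.73,   0.53,
    "FT7",     -0.86,   0.28,
    "FC3",     -0.47,   0.24,
    "FCz",      0.00,   0.27,
    "FC4",      0.47,   0.24,
    "FT8",      0.86,   0.28,
    "T7",      -0.90,   0.00,
    "C3",      -0.45,   0.00,
    "Cz",       0.00,   0.00,
    "C4",       0.45,   0.00,
    "T8",       0.90,   0.00,
    "TP7",     -0.86,  -0.28,
    "CP3",     -0.47,  -0.24,
    "CPz",      0.00,  -0.27,
    "CP4",      0.47,  -0.24,
    "TP8",      0.86,  -0.28,
    "P7",      -0.73,  -0.53,
    "P3",      -0.45,  -0.47,
    "Pz",       0.00,  -0.54,
    "P4",       0.45,  -0.47,
    "P8",       0.73,  -0.53,
    "O1",      -0.28,  -0.85,
    "Oz",       0.00,  -0.90,
    "O2",       0.28,  -0.85
  )
  pos$midline <- pos$x == 0
  if (!is.null(channels)) {
    missing <- setdiff(channels, pos$channel)
    if (length(missing) > 0) {
      rlang::abort(paste0("Unknown 10-20 labels: ", paste(missing, collapse = ", ")))
    }
    pos <- pos[match(channels, pos$channel), ]
  }
  pos
}

#' Default channel sets
#'
#' `montage_channels(32)` is the package's default 32-channel recording set;
#' `montage_channels(19)` is a reduced set used for fast simulations. Both
#' include the prefrontal electrodes (FP1, FPz, FP2, AF3, AF4) and the
#' midline chain needed by the downstream analyses.
#'
#' @param n Either 32 or 19.
#' @return Character vector of channel labels.
#' @export
montage_channels <- function(n = 32) {
  if (n == 32) {
    c("FP1", "FPz", "FP2", "AF3", "AF4",
      "F7", "F3", "Fz", "F4", "F8",
      "FT7", "FC3", "FCz", "FC4", "FT8",
      "T7", "C3", "Cz", "C4", "T8",
      "TP7", "CP3", "CPz", "CP4", "TP8",
      "P7", "P3", "Pz", "P4", "P8",
      "O1", "O2")
  } else if (n == 19) {
    c("FP1", "FPz", "FP2", "AF3", "AF4",
      "F7", "F3", "Fz", "F4", "F8",
      "C3", "Cz", "C4", "CPz",
      "P3", "Pz", "P4", "O1", "O2")
  } else {
    rlang::abort("`n` must be 32 or 19.")
  }
}
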