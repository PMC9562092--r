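#' Write a recording as a delimited matrix plus JSON sidecar
#'
#' The data matrix goes to `<path>.tsv` (channels in columns, one sample per
#' row) and the header (sampling rate, labels, 2-D positions, reference) to
#' `<path>.json`.
#'
#' @param rec An [eeg_recording].
#' @param path Output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  m <- t(rec$data)
  colnames(m) <- rec$labels
  utils::write.table(m, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  header <- list(fs = rec$fs, labels = rec$labels, reference = rec$reference,
                 positions = rec$positions)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path stem (no extension).
#' @return An [eeg_recording].
#' @export
read_recording <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- utils::read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                         check.names = FALSE)
  pos <- if (!is.null(header$positions)) tibble::as_tibble(header$positions) else NULL
  eeg_recording(t(as.matrix(m)), header$fs, header$labels,
                positions = pos, reference = header$reference)
}

#' Write / read an event or result table as TSV
#' @param x Data frame.
#' @param path Output file.
#' @return `path` invisibly, or the tibble when reading.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
}

#' Write / read a labelled adjacency matrix
#'
#' Delimited channels x channels matrix with a channel-label header row and
#' a leading label column.
#'
#' @param W Square matrix with dimnames.
#' @param path Output file.
#' @return `path` invisibly, or the matrix when reading.
#' @export
write_adjacency <- function(W, path) {
  df <- data.frame(channel = rownames(W), W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
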