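#' Tidy a microstate solution into a long template table
#'
#' @param x A `microstate_solution`.
#' @param ... Unused.
#' @return Tibble: template, channel, value.
#' @export
tidy.microstate_solution <- function(x, ...) {
  tpl <- x$templates
  ch <- colnames(tpl) %||% paste0("ch", seq_len(ncol(tpl)))
  tibble::tibble(
    template = rep(seq_len(nrow(tpl)), each = ncol(tpl)),
    channel = rep(ch, nrow(tpl)),
    value = as.numeric(t(tpl))
  )
}

#' One-row fit summary of a microstate solution
#'
#' @param x A `microstate_solution`.
#' @param ... Unused.
#' @return Tibble: K, gev, sigma2, cv, polarity.
#' @export
glance.microstate_solution <- function(x, ...) {
  tibble::tibble(K = x$K, gev = x$gev, sigma2 = x$sigma2, cv = x$cv,
                 polarity = x$polarity)
}

#' Tidy a PSI matrix into a long edge table
#'
#' @param x A `psi_matrix`.
#' @param ... Unused.
#' @return Tibble: source, target, psi, band.
#' @export
tidy.psi_matrix <- function(x, ...) {
  m <- x$psi
  tibble::tibble(
    source = rep(rownames(m), times = ncol(m)),
    target = rep(colnames(m), each = nrow(m)),
    psi = as.numeric(m),
    band = x$band
  )
}

#' Tidy graph metrics into a per-node table
#'
#' @param x A `graph_metrics` object.
#' @param ... Unused.
#' @return Tibble: node, cc, le.
#' @export
tidy.graph_metrics <- function(x, ...) {
  tibble::tibble(node = names(x$cc) %||% seq_along(x$cc),
                 cc = unname(x$cc), le = unname(x$le))
}

#' One-row summary of graph metrics
#'
#' @param x A `graph_metrics` object.
#' @param ... Unused.
#' @return Tibble: tau, cpl, ge, cc_mean, le_mean, n_finite_pairs.
#' @export
glance.graph_metrics <- function(x, ...) {
  tibble::tibble(tau = x$tau, cpl = x$cpl, ge = x$ge, cc_mean = x$cc_mean,
                 le_mean = x$le_mean, n_finite_pairs = x$n_finite_pairs)
}

#' Tidy a GFP series
#'
#' @param x A `gfp_series`.
#' @param ... Unused.
#' @return Tibble: time_s (when fs known), sample, gfp.
#' @export
tidy.gfp_series <- function(x, ...) {
  out <- tibble::tibble(sample = seq_along(x$values), gfp = x$values)
  if (!is.null(x$fs)) out$time_s <- (out$sample - 1) / x$fs
  out
}

#' Tidy an ERP waveform
#'
#' @param x An `erp_waveform`.
#' @param ... Unused.
#' @return Tibble: time_ms, amplitude, condition, electrode.
#' @export
tidy.erp_waveform <- function(x, ...) {
  tibble::tibble(
    time_ms = (x$tmin + (seq_along(x$values) - 1) / x$fs) * 1000,
    amplitude = x$values,
    condition = x$condition,
    electrode = x$electrode
  )
}
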