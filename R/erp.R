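#' Condition-wise ERP average at one electrode
#'
#' Pointwise mean across kept trials of one condition at one electrode.
#'
#' @param epochs An [eeg_epochs].
#' @param condition Condition label to average.
#' @param electrode Channel label.
#' @return An `erp_waveform`: list with `values` (uV per timepoint), `fs`,
#'   `tmin`, `condition`, `electrode`, `n_trials`.
#' @export
average_epochs <- function(epochs, condition, electrode) {
  ch <- match(electrode, epochs$labels)
  if (is.na(ch)) rlang::abort(paste0("Unknown electrode: ", electrode))
  sel <- epochs$kept & epochs$condition == condition
  if (!any(sel)) rlang::abort(paste0("No kept trials for condition ", condition))
  slab <- epochs$data[sel, ch, , drop = FALSE]
  vals <- if (sum(sel) == 1) {
    as.numeric(slab)
  } else {
    colMeans(matrix(slab, nrow = sum(sel)))
  }
  structure(
    list(values = vals, fs = epochs$fs, tmin = epochs$tmin,
         condition = condition, electrode = electrode, n_trials = sum(sel)),
    class = "erp_waveform"
  )
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s @ %s: %d samples, %d trials\n",
              x$condition, x$electrode, length(x$values), x$n_trials))
  invisible(x)
}

#' Measure an ERP component's amplitude and latency
#'
#' Amplitude is the extremum of the stated polarity inside the window
#' (maximum for positive components such as P2/P3, minimum for negative
#' ones); latency is its time. Ties resolve to the earliest sample.
#'
#' @param erp An `erp_waveform` (or bare numeric vector with `fs`/`tmin`).
#' @param component Component name tag (`"P2"`, `"P3"`, `"N3"`, ...).
#' @param window_ms Length-2 window `(lo, hi)` in ms relative to onset.
#'   Defaults per component: P2 150-275, P3 275-450, N3 3250-3450.
#' @param polarity `"positive"` or `"negative"`; default inferred from the
#'   component's leading letter.
#' @param fs,tmin Used when `erp` is a bare vector.
#' @return Tibble row: `component`, `amplitude` (uV), `latency_ms`,
#'   `window_lo_ms`, `window_hi_ms`.
#' @export
measure_component <- function(erp, component = "P2", window_ms = NULL,
                              polarity = NULL, fs = NULL, tmin = 0) {
  if (inherits(erp, "erp_waveform")) {
    vals <- erp$values
    fs <- erp$fs
    tmin <- erp$tmin
  } else {
    vals <- as.numeric(erp)
    if (is.null(fs)) rlang::abort("fs is required for a bare vector.")
  }
  window_ms <- window_ms %||% switch(component,
    P2 = c(150, 275), P3 = c(275, 450), N3 = c(3250, 3450),
    rlang::abort("No default window for this component; supply window_ms.")
  )
  polarity <- polarity %||%
    if (startsWith(toupper(component), "N")) "negative" else "positive"
  t_ms <- (tmin + (seq_along(vals) - 1) / fs) * 1000
  in_win <- which(t_ms >= window_ms[1] & t_ms <= window_ms[2])
  if (length(in_win) == 0) rlang::abort("Component window contains no samples.")
  w <- vals[in_win]
  idx <- if (polarity == "positive") which.max(w) else which.min(w)
  tibble::tibble(
    component = component,
    amplitude = w[idx],
    latency_ms = t_ms[in_win[idx]],
    window_lo_ms = window_ms[1],
    window_hi_ms = window_ms[2]
  )
}

# Vectorized one-way ANOVA across groups at every timepoint.
# x: list of trials x time matrices (one per condition).
pointwise_f <- function(x) {
  k <- length(x)
  ns <- vapply(x, nrow, integer(1))
  N <- sum(ns)
  n_t <- ncol(x[[1]])
  means <- vapply(x, colMeans, numeric(n_t))        # time x k
  grand <- as.numeric(means %*% ns) / N
  ss_between <- rowSums(sweep(means, 1, grand)^2 %*% diag(ns))
  ss_within <- numeric(n_t)
  for (g in seq_len(k)) {
    ss_within <- ss_within + colSums(sweep(x[[g]], 2, means[, g])^2)
  }
  df1 <- k - 1
  df2 <- N - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate within-group variance: p = 1 when the means agree too
  zero_w <- ss_within <= 0
  p[zero_w & ss_between <= 1e-24] <- 1
  p[zero_w & ss_between > 1e-24] <- 0
  f[zero_w] <- ifelse(ss_between[zero_w] > 1e-24, Inf, 0)
  list(f = f, p = p, df1 = df1, df2 = df2)
}

#' Pointwise one-way ANOVA across conditions
#'
#' At each timepoint, a one-way ANOVA compares per-trial amplitudes across
#' conditions at one electrode. Timepoints with `p <= alpha` are grouped
#' into contiguous runs, and runs shorter than `min_run_ms` are discarded
#' (isolated significant points are treated as noise; the analysis reports
#' contiguous periods).
#'
#' @param epochs An [eeg_epochs] (>= 2 conditions with >= 2 kept trials).
#' @param electrode Channel label.
#' @param alpha Pointwise significance level (default 0.05).
#' @param min_run_ms Minimum run length to report, ms (default 20).
#' @return List: `intervals` (tibble start_ms, end_ms), `p` (per-timepoint),
#'   `f`, `time_ms`.
#' @export
pointwise_anova <- function(epochs, electrode, alpha = 0.05, min_run_ms = 20) {
  ch <- match(electrode, epochs$labels)
  if (is.na(ch)) rlang::abort(paste0("Unknown electrode: ", electrode))
  conds <- unique(epochs$condition[epochs$kept])
  if (length(conds) < 2) rlang::abort("Pointwise ANOVA needs >= 2 conditions.")
  x <- lapply(conds, function(cond) {
    sel <- epochs$kept & epochs$condition == cond
    if (sum(sel) < 2) rlang::abort("Each condition needs >= 2 kept trials.")
    epochs$data[sel, ch, , drop = FALSE][, 1, , drop = TRUE]
  })
  res <- pointwise_f(x)
  t_ms <- epoch_times_ms(epochs)
  sig <- res$p <= alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & (t_ms[ends] - t_ms[starts]) >= min_run_ms
  intervals <- tibble::tibble(start_ms = t_ms[starts[keep]],
                              end_ms = t_ms[ends[keep]])
  list(intervals = intervals, p = res$p, f = res$f, time_ms = t_ms)
}

#' ERP summary table over electrodes and conditions
#'
#' Component measurements for every (condition, electrode) pair present in
#' the epochs.
#'
#' @param epochs An [eeg_epochs].
#' @param electrodes Channel labels (default the prefrontal set).
#' @param component Component tag for [measure_component()].
#' @param window_ms Optional component window override.
#' @return Tibble: condition, electrode, n_trials, component, amplitude,
#'   latency_ms, window bounds.
#' @export
erp_component_table <- function(epochs,
                                electrodes = c("FP1", "FPz", "FP2", "AF3", "AF4"),
                                component = "P2", window_ms = NULL) {
  conds <- unique(epochs$condition[epochs$kept])
  rows <- list()
  for (cond in conds) {
    for (el in electrodes) {
      wav <- average_epochs(epochs, cond, el)
      m <- measure_component(wav, component, window_ms)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        m, condition = cond, electrode = el, n_trials = wav$n_trials,
        .before = 1
      )
    }
  }
  dplyr::bind_rows(rows)
}
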