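#' Global field power
#'
#' GFP(t) is the root mean square across the average-referenced electrode
#' values at each instant: `sqrt(mean(u_i(t)^2))`. It is a
#' reference-independent measure of instantaneous response strength. Input
#' that is not average-referenced triggers a warning and is re-referenced.
#'
#' @param erp Numeric matrix, channels x time (uV), average-referenced.
#' @param fs Sampling rate, Hz (kept as metadata).
#' @param tol Tolerance on the per-sample channel mean before re-referencing.
#' @return An object of class `gfp_series`: list with `values` (uV per
#'   timepoint) and `fs`.
#' @export
gfp <- function(erp, fs = NULL, tol = 1e-6) {
  erp <- as.matrix(erp)
  mu <- colMeans(erp)
  if (max(abs(mu)) > tol) {
    rlang::warn("Input is not average-referenced; re-referencing before GFP.")
    erp <- sweep(erp, 2, mu)
  }
  structure(list(values = sqrt(colMeans(erp^2)), fs = fs),
            class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d timepoints, peak %.3g uV\n",
              length(x$values), max(x$values)))
  invisible(x)
}

#' GFP peak extraction
#'
#' Strict local maxima of the GFP curve, thinned so that no two retained
#' peaks are closer than `min_separation_ms` (the larger peak wins).
#' Topographies at GFP peaks are the high signal-to-noise maps fed to the
#' clustering.
#'
#' @param gfp_series A [gfp()] result (or bare numeric vector with `fs`).
#' @param min_separation_ms Minimum spacing between retained peaks, ms.
#' @param fs Sampling rate when `gfp_series` is a bare vector.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
gfp_peaks <- function(gfp_series, min_separation_ms = 10, fs = NULL) {
  if (inherits(gfp_series, "gfp_series")) {
    v <- gfp_series$values
    fs <- fs %||% gfp_series$fs
  } else {
    v <- as.numeric(gfp_series)
  }
  if (min_separation_ms < 0) rlang::abort("min_separation_ms must be >= 0.")
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (length(idx) == 0 || min_separation_ms == 0 || is.null(fs)) return(idx)
  min_gap <- min_separation_ms / 1000 * fs
  keep <- integer(0)
  for (i in idx[order(v[idx], decreasing = TRUE)]) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

# Spatial (Pearson) correlation between maps and template rows.
# maps: P x C, templates: K x C -> P x K matrix.
spatial_correlation <- function(maps, templates) {
  mc <- maps - rowMeans(maps)
  tc <- templates - rowMeans(templates)
  ms <- sqrt(rowSums(mc^2))
  ts <- sqrt(rowSums(tc^2))
  num <- mc %*% t(tc)
  den <- outer(ms, ts)
  out <- num / den
  out[!is.finite(out)] <- 0
  out
}

# Cluster template: polarity-sensitive mean or first principal component,
# unit-normalized.
cluster_template <- function(members, polarity) {
  if (is.null(dim(members))) members <- matrix(members, nrow = 1)
  if (polarity == "sensitive" || nrow(members) == 1) {
    tpl <- colMeans(members)
  } else {
    sv <- svd(members, nu = 0, nv = 1)
    tpl <- sv$v[, 1]
  }
  tpl / sqrt(sum(tpl^2))
}

# Labels for maps given unit-norm templates; ties -> lowest template index.
assign_labels <- function(maps, templates, polarity) {
  co <- spatial_correlation(maps, templates)
  fit <- if (polarity == "invariant") abs(co) else co
  max.col(fit, ties.method = "first")
}

# GEV of a labelling: GFP^2-weighted squared spatial correlation.
solution_gev <- function(maps, templates, labels, polarity) {
  co <- spatial_correlation(maps, templates)
  g2 <- rowMeans(maps^2)  # squared GFP of each (avg-ref) map
  r <- co[cbind(seq_len(nrow(maps)), labels)]
  sum(g2 * r^2) / sum(g2)
}

# Unexplained variance of the fit: mean over maps of the residual after
# projecting on the assigned unit-norm template, per Pascual-Marqui.
solution_sigma2 <- function(maps, templates, labels) {
  n_ch <- ncol(maps)
  a <- rowSums(maps * templates[labels, , drop = FALSE])
  sum(rowSums(maps^2) - a^2) / (nrow(maps) * (n_ch - 1))
}

new_microstate_solution <- function(K, templates, labels, gev, sigma2, cv,
                                    polarity, channel_labels = NULL) {
  colnames(templates) <- channel_labels
  structure(
    list(K = K, templates = templates, labels = labels, gev = gev,
         sigma2 = sigma2, cv = cv, polarity = polarity),
    class = "microstate_solution"
  )
}

#' @export
print.microstate_solution <- function(x, ...) {
  cat(sprintf("<microstate_solution> K = %d, GEV = %.3f, CV = %.4g (%s polarity)\n",
              x$K, x$gev, x$cv, x$polarity))
  invisible(x)
}

#' Topographic atomize & agglomerate hierarchical clustering (T-AAHC)
#'
#' Bottom-up clustering of scalp topographies. Every map starts as a
#' singleton cluster; at each step the cluster contributing least global
#' explained variance (GEV) is dissolved ("atomized") and each of its
#' members is reassigned to the surviving cluster with the highest spatial
#' correlation (absolute correlation when `polarity = "invariant"`).
#' Templates are the polarity-sensitive mean, or the first principal
#' component of member maps, unit-normalized. A solution is recorded at
#' every K in `[k_min, k_max]` on the way down.
#'
#' @param maps Numeric matrix, maps x channels (typically topographies at
#'   GFP peaks, average-referenced).
#' @param k_min,k_max Range of cluster counts to record.
#' @param polarity `"sensitive"` (evoked data default: component sign
#'   matters) or `"invariant"`.
#' @param channel_labels Optional channel names for the templates.
#' @return Named list of `microstate_solution` objects (`"K=4"`, ...).
#' @export
taahc <- function(maps, k_min = 2, k_max = 8,
                  polarity = c("sensitive", "invariant"),
                  channel_labels = colnames(maps)) {
  polarity <- match.arg(polarity)
  maps <- as.matrix(maps)
  P <- nrow(maps)
  if (k_max > P) rlang::abort("k_max cannot exceed the number of maps.")
  if (k_min < 1 || k_min > k_max) rlang::abort("Require 1 <= k_min <= k_max.")

  assignment <- seq_len(P)            # cluster id per map
  templates <- lapply(seq_len(P), function(i) cluster_template(maps[i, ], polarity))
  active <- seq_len(P)

  g2 <- rowMeans(maps^2)
  solutions <- list()

  snapshot <- function() {
    K <- length(active)
    tpl <- do.call(rbind, templates[active])
    lab <- match(assignment, active)
    gev <- solution_gev(maps, tpl, lab, polarity)
    s2 <- solution_sigma2(maps, tpl, lab)
    cv <- cv_criterion(s2, ncol(maps), K)
    new_microstate_solution(K, tpl, lab, gev, s2, cv, polarity, channel_labels)
  }

  cluster_contribution <- function(id) {
    members <- which(assignment == id)
    co <- spatial_correlation(maps[members, , drop = FALSE],
                              matrix(templates[[id]], nrow = 1))
    sum(g2[members] * co[, 1]^2)
  }

  if (length(active) >= k_min && length(active) <= k_max) {
    solutions[[paste0("K=", length(active))]] <- snapshot()
  }
  while (length(active) > k_min) {
    contrib <- vapply(active, cluster_contribution, numeric(1))
    worst <- active[which.min(contrib)]
    active <- setdiff(active, worst)
    orphans <- which(assignment == worst)
    tpl <- do.call(rbind, templates[active])
    co <- spatial_correlation(maps[orphans, , drop = FALSE], tpl)
    fit <- if (polarity == "invariant") abs(co) else co
    dest <- active[max.col(fit, ties.method = "first")]
    assignment[orphans] <- dest
    for (id in unique(dest)) {
      templates[[id]] <- cluster_template(maps[assignment == id, , drop = FALSE],
                                          polarity)
    }
    if (length(active) >= k_min && length(active) <= k_max) {
      solutions[[paste0("K=", length(active))]] <- snapshot()
    }
  }
  rev(solutions)  # ascending K
}

#' Cross-validation criterion for the number of microstate classes
#'
#' The predictive residual variance criterion:
#' `CV = sigma2 * ((n - 1) / (n - 1 - K))^2`, where `sigma2` is the mean
#' unexplained variance of the fit and `n` the channel count. Smaller is
#' better; the penalty term guards against overfitting K.
#'
#' @param residual_var Mean unexplained variance of the fit (uV^2).
#' @param n_channels Number of electrodes.
#' @param K Number of microstate classes.
#' @return The CV value.
#' @export
cv_criterion <- function(residual_var, n_channels, K) {
  if (n_channels <= K + 1) rlang::abort("Require n_channels > K + 1.")
  residual_var * ((n_channels - 1) / (n_channels - 1 - K))^2
}

#' Select the number of microstates by minimum CV
#'
#' @param solutions A list of `microstate_solution`s (from [taahc()]).
#' @return The K of the solution with minimal CV.
#' @export
select_k <- function(solutions) {
  cvs <- vapply(solutions, function(s) s$cv, numeric(1))
  solutions[[which.min(cvs)]]$K
}

#' Back-fit templates to a waveform
#'
#' Assigns every timepoint of an average-referenced ERP to the template with
#' maximal spatial correlation (absolute correlation when polarity-
#' invariant; ties to the lowest template index), then merges contiguous
#' equal labels into segments. Labels are invariant to global scaling of the
#' input.
#'
#' @param erp Channels x time matrix (average-referenced).
#' @param templates K x channels matrix of unit-norm templates.
#' @param polarity `"sensitive"` or `"invariant"`.
#' @param fs Sampling rate, Hz (for the segment table times).
#' @param tmin Time of the first sample, seconds (default 0).
#' @return List with `labels` (per-timepoint template index) and
#'   `segment_table` (tibble: start_ms, end_ms, template).
#' @export
backfit <- function(erp, templates, polarity = c("sensitive", "invariant"),
                    fs = NULL, tmin = 0) {
  polarity <- match.arg(polarity)
  erp <- as.matrix(erp)
  labels <- assign_labels(t(erp), as.matrix(templates), polarity)
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  if (is.null(fs)) {
    seg <- tibble::tibble(start = starts, end = ends, template = runs$values)
  } else {
    t_ms <- (tmin + (seq_along(labels) - 1) / fs) * 1000
    seg <- tibble::tibble(start_ms = t_ms[starts], end_ms = t_ms[ends],
                          template = runs$values)
  }
  list(labels = labels, segment_table = seg)
}

#' Match microstate templates across conditions
#'
#' Greedy one-to-one pairing of each condition's templates against the first
#' (reference) condition, in descending absolute spatial correlation,
#' reporting the correlation of each matched pair.
#'
#' @param solutions Named list of `microstate_solution`s (>= 2), one per
#'   condition; the first is the reference.
#' @return Tibble: `condition`, `ref_template`, `template`, `correlation`.
#' @export
match_across_conditions <- function(solutions) {
  if (length(solutions) < 2) rlang::abort("Need >= 2 solutions to match.")
  if (is.null(names(solutions))) {
    names(solutions) <- paste0("condition", seq_along(solutions))
  }
  ref <- solutions[[1]]$templates
  out <- lapply(seq_along(solutions)[-1], function(i) {
    other <- solutions[[i]]$templates
    co <- abs(spatial_correlation(ref, other))
    pairs <- list()
    while (any(is.finite(co))) {
      best <- arrayInd(which.max(co), dim(co))
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        condition = names(solutions)[i],
        ref_template = best[1], template = best[2],
        correlation = co[best]
      )
      co[best[1], ] <- -Inf
      co[, best[2]] <- -Inf
    }
    dplyr::arrange(dplyr::bind_rows(pairs), .data$ref_template)
  })
  dplyr::bind_rows(out)
}

#' Full microstate analysis of one condition's ERP
#'
#' GFP, GFP-peak extraction, T-AAHC over a K range, CV model selection, and
#' back-fitting of the selected templates onto the full waveform.
#'
#' @param erp Channels x time matrix (average-referenced grand average).
#' @param fs Sampling rate, Hz.
#' @param k_min,k_max K range handed to [taahc()].
#' @param polarity Polarity handling.
#' @param min_separation_ms GFP-peak thinning, ms.
#' @param channel_labels Channel names.
#' @return List: `gfp`, `peaks`, `solutions`, `k_opt`, `solution` (at
#'   `k_opt`), `segmentation` (backfit result).
#' @export
microstate_analysis <- function(erp, fs, k_min = 2, k_max = 8,
                                polarity = "sensitive",
                                min_separation_ms = 10,
                                channel_labels = rownames(erp)) {
  g <- gfp(erp, fs)
  peaks <- gfp_peaks(g, min_separation_ms)
  if (length(peaks) < k_max) {
    rlang::abort("Fewer GFP peaks than k_max; lower k_max or the peak spacing.")
  }
  sols <- taahc(t(erp)[peaks, , drop = FALSE], k_min, k_max,
                polarity = polarity, channel_labels = channel_labels)
  k_opt <- select_k(sols)
  sol <- sols[[paste0("K=", k_opt)]]
  segm <- backfit(erp, sol$templates, polarity = polarity, fs = fs)
  list(gfp = g, peaks = peaks, solutions = sols, k_opt = k_opt,
       solution = sol, segmentation = segm)
}
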