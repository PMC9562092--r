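new_stat_result <- function(test, statistic, df, p, effect_direction,
                            n1, n2 = NA_integer_, r = NA_real_, note = NA_character_) {
  tibble::tibble(
    test = test, statistic = statistic, df = df,
    p = pmin(1, pmax(0, p)), effect_direction = effect_direction,
    n1 = n1, n2 = n2, r = r, note = note
  )
}

#' Matched-samples (paired) t-test
#'
#' Two-sided paired t-test on post - pre differences (used to verify that
#' emotional stimulation shifted valence). Degenerate cases are guarded:
#' identical vectors give t = 0, p = 1; zero-variance differences with a
#' nonzero mean give p ~ 0 with a note.
#'
#' @param pre,post Equal-length numeric vectors (n >= 3).
#' @return One-row tibble (test, statistic, df, p, effect_direction, n1, r).
#' @export
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) rlang::abort("pre/post lengths differ.")
  n <- length(pre)
  if (n < 3) rlang::abort("Paired t-test needs n >= 3.")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(new_stat_result("paired_t", 0, n - 1, 1, 0L, n))
    }
    return(new_stat_result("paired_t", sign(mean(d)) * Inf, n - 1, 0,
                           as.integer(sign(mean(d))), n,
                           note = "zero-variance differences"))
  }
  tt <- stats::t.test(d)
  new_stat_result("paired_t", unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, as.integer(sign(mean(d))), n)
}

#' One-way analysis of variance
#'
#' F and p from between/within sums of squares with df (k - 1, N - k)
#' (used on decision accuracy and reaction time across the four condition
#' blocks). Degenerate within-group variance gives p = 1 when group means
#' agree and p = 0 otherwise.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @return One-row tibble.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2) rlang::abort("ANOVA needs >= 2 groups.")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    rlang::abort("Each group needs >= 2 values.")
  }
  ns <- vapply(groups, length, integer(1))
  N <- sum(ns)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(means * ns) / N
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ss_w <= 0) {
    if (ss_b <= 1e-24) return(new_stat_result("oneway_anova", 0, df1, 1, 0L, N))
    return(new_stat_result("oneway_anova", Inf, df1, 0, 0L, N,
                           note = "zero within-group variance"))
  }
  f <- (ss_b / df1) / (ss_w / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  new_stat_result("oneway_anova", f, df1, p, 0L, N)
}

#' Split blocks into top/bottom accuracy groups
#'
#' group1 holds the k blocks with the highest correct counts, group2 the k
#' lowest. Ties are broken deterministically by ascending (subject, block)
#' order, so with all-equal accuracies group1 is the first k rows and
#' group2 the last k.
#'
#' @param blocks Tibble with columns `correct` and (for the tie-break)
#'   `subject`, `block`.
#' @param k Group size (default 16).
#' @return List of tibbles `group1`, `group2`.
#' @export
split_by_accuracy <- function(blocks, k = 16) {
  n <- nrow(blocks)
  if (2 * k > n) rlang::abort("2k exceeds the number of blocks.")
  if (k == 0) return(list(group1 = blocks[0, ], group2 = blocks[0, ]))
  ord_cols <- intersect(c("subject", "block"), names(blocks))
  ord <- do.call(order, c(list(-blocks$correct), blocks[ord_cols]))
  sorted <- blocks[ord, ]
  list(group1 = sorted[seq_len(k), ],
       group2 = sorted[(n - k + 1):n, ])
}

#' Independent-samples (Welch) t-test
#'
#' Two-sided Welch t-test (unequal variances) between two groups, used on
#' whole-brain-average local measures of the high- vs low-accuracy groups.
#'
#' @param g1,g2 Numeric vectors (each n >= 2).
#' @return One-row tibble.
#' @export
independent_ttest <- function(g1, g2) {
  if (length(g1) < 2 || length(g2) < 2) rlang::abort("Each group needs n >= 2.")
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    if (mean(g1) == mean(g2)) {
      return(new_stat_result("welch_t", 0, length(g1) + length(g2) - 2, 1, 0L,
                             length(g1), length(g2)))
    }
    return(new_stat_result("welch_t", sign(mean(g1) - mean(g2)) * Inf,
                           length(g1) + length(g2) - 2, 0,
                           as.integer(sign(mean(g1) - mean(g2))),
                           length(g1), length(g2),
                           note = "zero variance in both groups"))
  }
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  new_stat_result("welch_t", unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, as.integer(sign(mean(g1) - mean(g2))),
                  length(g1), length(g2))
}

#' Pearson correlation with t-based p-value
#'
#' r and its two-sided p-value via the t transform on n - 2 degrees of
#' freedom (used between graph metrics and decision accuracy).
#'
#' @param x,y Equal-length finite numeric vectors (n >= 3).
#' @return One-row tibble (with `r` filled in).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x/y lengths differ.")
  if (length(x) < 3) rlang::abort("Pearson correlation needs n >= 3.")
  if (!all(is.finite(x)) || !all(is.finite(y))) rlang::abort("Values must be finite.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Zero variance; correlation undefined.")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  new_stat_result("pearson", unname(ct$statistic), unname(ct$parameter),
                  ct$p.value, as.integer(sign(ct$estimate)),
                  length(x), r = unname(ct$estimate))
}

#' Benjamini-Hochberg adjustment helper
#'
#' Optional multiple-testing correction across a column of p-values (the
#' primary analyses report uncorrected p, as is conventional for these
#' tables; this exposes the corrected version).
#'
#' @param results Tibble with a `p` column.
#' @return The tibble with an added `p_adj` column.
#' @export
adjust_bh <- function(results) {
  dplyr::mutate(results, p_adj = stats::p.adjust(.data$p, method = "BH"))
}

#' Per-electrode topographic summary by group
#'
#' Group-wise mean of a per-electrode metric, with montage coordinates and a
#' midline flag attached, for scalp-map rendering and midline-region
#' reporting. Electrodes without a position are excluded with a warning.
#'
#' @param values Tibble with columns `electrode`, `value` and `group`.
#' @param positions Montage tibble (`channel`, `x`, `y`, `midline`);
#'   default the shipped 10-20 table.
#' @return Tibble: group, electrode, mean_value, x, y, midline.
#' @export
topographic_summary <- function(values, positions = ten_twenty_montage()) {
  missing <- setdiff(unique(values$electrode), positions$channel)
  if (length(missing) > 0) {
    rlang::warn(paste0("No position for: ", paste(missing, collapse = ", "),
                       "; excluded."))
    values <- dplyr::filter(values, !.data$electrode %in% missing)
  }
  out <- values |>
    dplyr::group_by(.data$group, .data$electrode) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop") |>
    dplyr::left_join(
      dplyr::select(positions, electrode = "channel", "x", "y", "midline"),
      by = "electrode"
    )
  dplyr::arrange(out, .data$group, .data$electrode)
}
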