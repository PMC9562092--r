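#' Plot a GFP curve with its peaks
#'
#' @param object A `gfp_series`.
#' @param peaks Optional peak indices from [gfp_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gfp_series <- function(object, peaks = NULL, ...) {
  df <- tidy(object)
  xvar <- if ("time_s" %in% names(df)) "time_s" else "sample"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$gfp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "time_s") "Time (s)" else "Sample",
                  y = "GFP (uV)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(data = df[peaks, ], colour = "red", size = 1)
  }
  p
}

#' Plot microstate templates as scalp point maps
#'
#' @param object A `microstate_solution` (templates need channel names
#'   present in the 10-20 montage).
#' @param ... Unused.
#' @return A ggplot, faceted by template.
#' @export
autoplot.microstate_solution <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::left_join(ten_twenty_montage(), by = "channel") |>
    dplyr::filter(!is.na(.data$x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_wrap(~template) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "uV (norm.)")
}

#' Heatmap of a PSI matrix
#'
#' @param object A `psi_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map (rows lead columns for positive entries).
#' @export
autoplot.psi_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$psi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(title = paste("PSI,", object$band), x = "target (led)",
                  y = "source (leading)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Interpolated scalp map of a topographic summary
#'
#' Inverse-distance-weighted interpolation of per-electrode values onto a
#' grid inside the unit head disc, one facet per group.
#'
#' @param summary_tbl Output of [topographic_summary()].
#' @param resolution Grid points per axis.
#' @return A ggplot.
#' @export
plot_topography <- function(summary_tbl, resolution = 60) {
  grid <- tidyr::crossing(gx = seq(-1, 1, length.out = resolution),
                          gy = seq(-1, 1, length.out = resolution)) |>
    dplyr::filter(.data$gx^2 + .data$gy^2 <= 1)
  interp <- function(df) {
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      d2 <- (df$x - grid$gx[i])^2 + (df$y - grid$gy[i])^2
      if (any(d2 < 1e-12)) return(df$mean_value[which.min(d2)])
      w <- 1 / d2
      sum(w * df$mean_value) / sum(w)
    }, numeric(1))
    dplyr::mutate(grid, value = vals)
  }
  df <- summary_tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~interp(.x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gx, y = .data$gy,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = summary_tbl,
                        ggplot2::aes(x = .data$x, y = .data$y), fill = NA,
                        shape = 21) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = mean(summary_tbl$mean_value)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Overlayed condition ERPs at one electrode
#'
#' @param epochs An [eeg_epochs].
#' @param electrode Channel label.
#' @param intervals Optional significance intervals tibble (from
#'   [pointwise_anova()]) shaded underneath.
#' @return A ggplot.
#' @export
plot_erp <- function(epochs, electrode, intervals = NULL) {
  conds <- unique(epochs$condition[epochs$kept])
  df <- dplyr::bind_rows(lapply(conds, function(cond) {
    tidy(average_epochs(epochs, cond, electrode))
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms,
                                        y = .data$amplitude,
                                        colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (uV)",
                  title = electrode) +
    ggplot2::theme_minimal()
  if (!is.null(intervals) && nrow(intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = intervals,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE, alpha = 0.15)
  }
  p
}
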