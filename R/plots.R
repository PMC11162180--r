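#' Plot a time-frequency map
#'
#' Raster of baseline-normalized log power over the canonical gait cycle,
#' with vertical lines at the canonical gait-event latencies.
#'
#' @param object A `tf_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_map <- function(object, ...) {
  df <- tidy(object)
  lat <- tibble::tibble(
    event = toupper(names(object$canonical_latencies)),
    time_pct = unname(object$canonical_latencies)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_pct, .data$freq_hz,
                                   fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(data = lat,
                        ggplot2::aes(xintercept = .data$time_pct),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "gait cycle (%)", y = "frequency (Hz)",
                  fill = "dB")
}

#' Plot the significant clusters of a permutation test
#'
#' Raster of the paired t statistic with the significant-cluster mask
#' outlined by tiles.
#'
#' @param object A `cluster_result`.
#' @param freqs,times Optional axis grids; defaults to matrix indices.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, freqs = NULL, times = NULL, ...) {
  nr <- nrow(object$t)
  nc <- ncol(object$t)
  freqs <- freqs %||% seq_len(nr)
  times <- times %||% seq_len(nc)
  df <- tibble::tibble(
    freq = rep(freqs, times = nc),
    time = rep(times, each = nr),
    t = as.vector(object$t),
    significant = as.vector(object$significant_mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t)) +
    ggplot2::geom_tile(data = df[df$significant, , drop = FALSE],
                       fill = NA, colour = "black", linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "time", y = "frequency", fill = "t")
}

#' Stride-level step length asymmetry time course
#'
#' @param strides A stride tibble with `stride_index`, `sla` and,
#'   optionally, `is_asymmetric` and `subcondition`.
#' @param normalized Plot `sla_normalized` when present.
#' @return A ggplot.
#' @export
plot_sla_timecourse <- function(strides, normalized = FALSE) {
  ycol <- if (normalized && "sla_normalized" %in% names(strides)) {
    "sla_normalized"
  } else "sla"
  p <- ggplot2::ggplot(strides,
                       ggplot2::aes(.data$stride_index, .data[[ycol]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "stride", y = "step length asymmetry")
  if ("is_asymmetric" %in% names(strides)) {
    p <- p + ggplot2::geom_point(
      data = strides[strides$is_asymmetric, , drop = FALSE],
      colour = "red", size = 0.6)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
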