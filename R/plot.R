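#' Plot amplification curves
#'
#' Raw fluorescence against cycle, one line per well, coloured by gene.
#' Optionally overlays a Savitzky-Golay smoothed trace; the smoothing is
#' display-only and never enters quantification.
#'
#' @param plate Long-format curves tibble.
#' @param smooth_window,smooth_order If `smooth_window` is not `NULL`, a
#'   smoothed overlay is drawn with [smooth_for_display()].
#' @return A ggplot object.
#' @export
plot_amplification <- function(plate, smooth_window = NULL, smooth_order = 2) {
  plate <- validate_plate(plate)
  p <- ggplot2::ggplot(plate, ggplot2::aes(x = .data$cycle,
                                           y = .data$fluorescence,
                                           group = .data$well,
                                           colour = .data$gene)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Cycle", y = "Fluorescence (a.u.)", colour = "Gene") +
    ggplot2::theme_minimal()
  if (!is.null(smooth_window)) {
    sm <- plate |>
      group_by(.data$well) |>
      mutate(fluorescence = smooth_for_display(
        dplyr::pick("cycle", "fluorescence"),
        window = smooth_window, order = smooth_order)) |>
      ungroup()
    p <- p + ggplot2::geom_line(data = sm, linetype = "dashed")
  }
  p
}

#' Diagnostic plot of one Gompertz fit
#'
#' Raw points, the fitted sigmoid, and vertical markers at the
#' second-derivative maximum and the quantification cycle.
#'
#' @param object A converged `gompertz_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gompertz_fit
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  stopifnot(isTRUE(object$converged))
  sdm <- sdm_location(object)
  cq <- quantification_cycle(object)
  grid <- tibble(cycle = seq(1, max(object$data$cycle), by = 0.1))
  grid$fit <- gompertz_value(object, grid$cycle)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$cycle, y = .data$fluorescence)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = sdm$x_sdm, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cq, linetype = "dotted") +
    ggplot2::labs(x = "Cycle", y = "Fluorescence (a.u.)",
                  title = sprintf("Cq = %.2f (dotted), SDM = %.2f (dashed)",
                                  cq, sdm$x_sdm)) +
    ggplot2::theme_minimal()
}

#' Dilution-series recovery plot
#'
#' Normalized observed initial target quantity against normalized known
#' concentration on log10 axes, per gene, with the identity line an unbiased
#' method should follow.
#'
#' @param f0_table Table with `gene`, `concentration`, `f0` (raw scale).
#' @return A ggplot object.
#' @export
plot_dilution_series <- function(f0_table) {
  norm <- normalize_f0(f0_table)
  ggplot2::ggplot(norm, ggplot2::aes(x = log10(.data$nc),
                                     y = log10(.data$f0_norm),
                                     colour = .data$gene)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log10 normalized concentration",
                  y = "log10 normalized F0", colour = "Gene") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
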