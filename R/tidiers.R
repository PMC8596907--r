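#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gompertz fit
#'
#' @param x A `gompertz_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`, `estimate`).
#' @method tidy gompertz_fit
#' @export
tidy.gompertz_fit <- function(x, ...) {
  tibble(term = c("y0", "ymax", "b", "x0"),
         estimate = c(x$y0, x$ymax, x$b, x$x0))
}

#' One-row fit summary of a Gompertz fit
#'
#' @param x A `gompertz_fit`.
#' @param ... Unused.
#' @return Tibble with `rss`, `n_iter`, `converged`, `status`, `n_cycles`.
#' @method glance gompertz_fit
#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble(rss = x$rss, n_iter = x$n_iter, converged = x$converged,
         status = x$status, n_cycles = nrow(x$data))
}

#' Tidy a rank-synthesis result
#'
#' @param x A `rank_synthesis`.
#' @param ... Unused.
#' @return The per-method ranks tibble (best first).
#' @method tidy rank_synthesis
#' @export
tidy.rank_synthesis <- function(x, ...) x$ranks

#' One-row summary of a rank-synthesis result
#'
#' @param x A `rank_synthesis`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p_value`, `n_methods`, `n_blocks`.
#' @method glance rank_synthesis
#' @export
glance.rank_synthesis <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n_methods = x$n_methods, n_blocks = x$n_blocks)
}

#' Tidy an indicator report
#'
#' @param x An `indicator_report`.
#' @param ... Unused.
#' @return The per-gene indicator tibble.
#' @method tidy indicator_report
#' @export
tidy.indicator_report <- function(x, ...) x$per_gene

#' One-row summary of an indicator report
#'
#' @param x An `indicator_report`.
#' @param ... Unused.
#' @return Tibble of the six dataset-level indicators.
#' @method glance indicator_report
#' @export
glance.indicator_report <- function(x, ...) {
  tibble(bias_ratio_dev = x$bias_ratio_dev, bias_slope_dev = x$bias_slope_dev,
         mean_relative_error = x$mean_relative_error, mean_cv = x$mean_cv,
         mean_precision = x$mean_precision, resolution_fold = x$resolution_fold)
}
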