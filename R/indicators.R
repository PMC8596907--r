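#' Normalize observed initial target quantities against the dilution design
#'
#' Puts concentrations and fluorescence-derived quantities on one scale:
#' within each gene, observed `f0` is divided by the mean `f0` of that gene's
#' highest-concentration replicate group, and known concentrations are
#' divided by the highest concentration (`nc`, normalized concentration, top
#' level = 1). After normalization the mean of the top group equals 1
#' exactly, for both scales, so every indicator is invariant to per-gene
#' fluorescence scaling.
#'
#' @param f0_table Data frame with columns `gene`, `concentration`, `f0`
#'   (e.g. rows of [analyze_plate()] output with `status == "ok"`). Rows with
#'   missing `f0` or `concentration` are dropped.
#' @return The table with added columns `nc` and `f0_norm`.
#' @export
normalize_f0 <- function(f0_table) {
  df <- as_tibble(f0_table) |>
    filter(!is.na(.data$f0), !is.na(.data$concentration))
  if (nrow(df) == 0) {
    abort("No usable (f0, concentration) rows.", class = "cqman_design_error")
  }
  df |>
    group_by(.data$gene) |>
    mutate(
      nc = .data$concentration / max(.data$concentration),
      f0_norm = {
        top <- .data$f0[.data$concentration == max(.data$concentration)]
        if (length(top) == 0) {
          abort(sprintf("Gene '%s' lacks a top-concentration group.",
                        first(.data$gene)),
                class = "cqman_design_error")
        }
        .data$f0 / mean(top)
      }
    ) |>
    ungroup()
}

#' Bias of the extreme-concentration ratio
#'
#' For each gene, the ratio of mean normalized F0 at the two extreme
#' concentration levels; for a 5-point 10-fold series read high-over-low the
#' expected ratio is 10,000, read low-over-high on a 4-point series it is
#' 0.001. The indicator is the mean over genes of the absolute deviation of
#' the observed ratio from the expected one.
#'
#' @param f0_table Normalized table from [normalize_f0()].
#' @param expected_ratio The design's expected extreme ratio.
#' @param orientation `"high_over_low"` or `"low_over_high"`.
#' @return Mean absolute deviation from the expected ratio (scalar).
#' @export
bias_ratio <- function(f0_table, expected_ratio,
                       orientation = c("high_over_low", "low_over_high")) {
  orientation <- match.arg(orientation)
  per_gene <- f0_table |>
    group_by(.data$gene) |>
    summarise(ratio = {
      hi <- mean(.data$f0_norm[.data$nc == max(.data$nc)])
      lo <- mean(.data$f0_norm[.data$nc == min(.data$nc)])
      if (orientation == "high_over_low") hi / lo else lo / hi
    }, .groups = "drop")
  mean(abs(per_gene$ratio - expected_ratio))
}

#' Bias of the log-log regression slope
#'
#' Ordinary least-squares slope of `log10(f0_norm)` on `log10(nc)` per gene;
#' an unbiased method has slope 1. Returns the mean over genes of
#' `|slope - 1|`.
#'
#' @param f0_table Normalized table from [normalize_f0()].
#' @return Mean absolute slope deviation (scalar).
#' @export
bias_slope <- function(f0_table) {
  per_gene <- f0_table |>
    group_by(.data$gene) |>
    summarise(slope = {
      if (length(unique(.data$nc)) < 3) {
        abort("bias_slope() needs at least 3 distinct concentration levels.",
              class = "cqman_design_error")
      }
      coef(lm(log10(.data$f0_norm) ~ log10(.data$nc)))[[2]]
    }, .groups = "drop")
  mean(abs(per_gene$slope - 1))
}

#' Mean absolute relative error of F0 against the known concentration
#'
#' Per well, \eqn{RE = (F_0 - NC)/NC} on the normalized scales; the
#' indicator is the mean of `|RE|` over all dilution-series wells of all
#' genes.
#'
#' @param f0_table Normalized table from [normalize_f0()].
#' @return Mean absolute relative error (scalar).
#' @export
relative_error <- function(f0_table) {
  mean(abs((f0_table$f0_norm - f0_table$nc) / f0_table$nc))
}

#' Mean coefficient of variation of replicate groups
#'
#' Per gene and concentration level, sample SD of normalized F0 divided by
#' the group mean, times 100; averaged over levels within a gene, then over
#' genes.
#'
#' @param f0_table Normalized table from [normalize_f0()].
#' @return Mean CV in percent (scalar).
#' @export
coefficient_of_variation <- function(f0_table) {
  per_gene <- f0_table |>
    group_by(.data$gene, .data$nc) |>
    filter(dplyr::n() >= 2) |>   # a lone survivor has no dispersion to measure
    summarise(cv = 100 * sd(.data$f0_norm) / mean(.data$f0_norm),
              .groups = "drop_last") |>
    summarise(cv = mean(.data$cv), .groups = "drop")
  mean(per_gene$cv)
}

#' Mean within-replicate-group variance (precision)
#'
#' Sample variance of normalized F0 within each replicate group (gene x
#' level), averaged over groups within a gene, then over genes. Should be
#' small and equal across methods; it reflects only random variation in
#' procedure and fluorescence measurement.
#'
#' @param f0_table Normalized table from [normalize_f0()].
#' @return Mean within-group variance (scalar).
#' @export
precision_within_group <- function(f0_table) {
  per_gene <- f0_table |>
    group_by(.data$gene, .data$nc) |>
    filter(dplyr::n() >= 2) |>
    summarise(v = var(.data$f0_norm), .groups = "drop_last") |>
    summarise(v = mean(.data$v), .groups = "drop")
  mean(per_gene$v)
}

#' Resolution as a detectable fold difference
#'
#' Per gene, ordinary least-squares regression of `log10(nc)` (true input)
#' on `log10(f0_norm)`; at each level's mean `log10(f0_norm)` the half-width
#' `h` of the two-sided prediction interval (default 95%) is computed in
#' log10 units and converted to a fold deviation `10^h`. The geometric mean
#' of the folds over levels is the gene's resolution, averaged over genes.
#' A value of 1 means zero residual scatter; about 2 means a 2-fold input
#' difference is what the method can resolve at the 5% level.
#'
#' @param f0_table Normalized table from [normalize_f0()].
#' @param confidence Coverage of the prediction interval (default 0.95).
#' @return Mean resolution fold (scalar, >= 1).
#' @export
resolution_fold <- function(f0_table, confidence = 0.95) {
  per_gene <- f0_table |>
    group_by(.data$gene) |>
    summarise(fold = {
      if (length(unique(.data$nc)) < 3) {
        abort("resolution_fold() needs at least 3 concentration levels.",
              class = "cqman_design_error")
      }
      dat <- data.frame(x = log10(.data$f0_norm), y = log10(.data$nc))
      m <- lm(y ~ x, data = dat)
      at <- tapply(dat$x, dat$y, mean)
      pr <- suppressWarnings(
        predict(m, newdata = data.frame(x = as.numeric(at)),
                interval = "prediction", level = confidence)
      )
      h <- (pr[, "upr"] - pr[, "lwr"]) / 2
      exp(mean(log(10^h)))
    }, .groups = "drop")
  mean(per_gene$fold)
}

#' Full six-indicator report for one method on one dilution-series dataset
#'
#' Convenience wrapper running [normalize_f0()] and all indicator
#' computations, with per-gene detail.
#'
#' @param f0_table Data frame with `gene`, `concentration`, `f0` (raw scale).
#' @param expected_ratio,orientation Passed to [bias_ratio()].
#' @param confidence Passed to [resolution_fold()].
#' @return A list of class `indicator_report`: scalar indicators
#'   `bias_ratio_dev`, `bias_slope_dev`, `mean_relative_error`, `mean_cv`,
#'   `mean_precision`, `resolution_fold`, plus a `per_gene` tibble.
#' @export
indicator_report <- function(f0_table, expected_ratio = 1e4,
                             orientation = c("high_over_low", "low_over_high"),
                             confidence = 0.95) {
  orientation <- match.arg(orientation)
  norm <- normalize_f0(f0_table)
  per_gene <- norm |>
    group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      df$gene <- key$gene
      tibble(
        bias_ratio_dev = bias_ratio(df, expected_ratio, orientation),
        bias_slope_dev = bias_slope(df),
        mean_relative_error = relative_error(df),
        mean_cv = coefficient_of_variation(df),
        mean_precision = precision_within_group(df),
        resolution_fold = resolution_fold(df, confidence)
      )
    }) |>
    ungroup()
  structure(list(
    bias_ratio_dev = bias_ratio(norm, expected_ratio, orientation),
    bias_slope_dev = bias_slope(norm),
    mean_relative_error = relative_error(norm),
    mean_cv = coefficient_of_variation(norm),
    mean_precision = precision_within_group(norm),
    resolution_fold = resolution_fold(norm, confidence),
    per_gene = per_gene
  ), class = "indicator_report")
}

#' @export
print.indicator_report <- function(x, ...) {
  cat("<indicator_report> (lower is better; resolution 1 = perfect)\n")
  cat(sprintf("  bias (extreme ratio deviation): %.6g\n", x$bias_ratio_dev))
  cat(sprintf("  bias (|slope - 1|):             %.6g\n", x$bias_slope_dev))
  cat(sprintf("  mean |relative error|:          %.6g\n", x$mean_relative_error))
  cat(sprintf("  mean CV:                        %.4g%%\n", x$mean_cv))
  cat(sprintf("  mean within-group variance:     %.6g\n", x$mean_precision))
  cat(sprintf("  resolution (fold):              %.6g\n", x$resolution_fold))
  cat(sprintf("  genes: %d\n", nrow(x$per_gene)))
  invisible(x)
}

#' Write an indicator report as JSON
#'
#' @param report An `indicator_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicator_report <- function(report, path) {
  out <- report[c("bias_ratio_dev", "bias_slope_dev", "mean_relative_error",
                  "mean_cv", "mean_precision", "resolution_fold")]
  out$per_gene <- report$per_gene
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
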