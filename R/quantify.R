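#' Quantification threshold from a fitted curve
#'
#' The threshold fluorescence is the midpoint between the fitted baseline and
#' the fluorescence at the second-derivative maximum:
#' \eqn{F_q = (y_0 + F_{SDM})/2}. Because \eqn{F_{SDM}} sits at a fixed
#' fraction of the amplitude, so does \eqn{F_q}, which makes the derived
#' quantification cycle insensitive to fluorescence scaling.
#'
#' @param fit A converged `gompertz_fit`.
#' @param sdm The SDM point from [sdm_location()] (one-row data frame with
#'   `f_sdm`).
#' @return The threshold fluorescence (scalar).
#' @export
quantification_threshold <- function(fit, sdm = sdm_location(fit)) {
  if (!isTRUE(fit$converged)) {
    abort("quantification_threshold() requires a converged fit.",
          class = "cqman_state_error")
  }
  (fit$y0 + sdm$f_sdm[1]) / 2
}

#' Quantification cycle: invert the Gompertz model at a threshold
#'
#' Solves \eqn{y(C_q) = F_q} analytically:
#' \deqn{C_q = x_0 - b \ln\left(-\ln\frac{F_q - y_0}{y_{max} - y_0}\right).}
#' With the midpoint threshold of [quantification_threshold()], the
#' quantification cycle always falls a fixed multiple of `b` before the SDM:
#' \eqn{C_q - x_{SDM} = -b\,\ln(1 + \ln 2 / u^*) \approx -0.2349\,b},
#' i.e. inside the exponential phase by construction.
#'
#' @param fit A converged `gompertz_fit`.
#' @param fq Threshold fluorescence, strictly between `y0` and `ymax`.
#' @return The fractional quantification cycle (scalar).
#' @export
quantification_cycle <- function(fit, fq = quantification_threshold(fit)) {
  if (!isTRUE(fit$converged)) {
    abort("quantification_cycle() requires a converged fit.",
          class = "cqman_state_error")
  }
  frac <- (fq - fit$y0) / (fit$ymax - fit$y0)
  if (!is.finite(frac) || frac <= 0 || frac >= 1) {
    abort("`fq` must lie strictly between y0 and ymax.",
          class = "cqman_domain_error")
  }
  fit$x0 - fit$b * log(-log(frac))
}

#' Integer-cycle window for the exponential-phase efficiency fit
#'
#' The exponential phase runs from the quantification cycle to the SDM. The
#' raw span covers only about `0.235 * b` cycles, usually fewer than the
#' points a three-parameter fit needs, so the window of integer cycles in
#' `[ceiling(cq), floor(x_sdm)]` is extended backwards one cycle at a time
#' (never below cycle 1, never past the SDM) until it holds at least
#' `min_points` cycles.
#'
#' @param cq Quantification cycle.
#' @param x_sdm Second-derivative-maximum cycle; must satisfy
#'   `cq < x_sdm <= n_cycles`.
#' @param n_cycles Number of cycles in the curve.
#' @param min_points Minimum number of cycles required (>= 4).
#' @return Sorted integer vector of cycles, or `NULL` when `min_points`
#'   cannot be reached within `[1, floor(x_sdm)]` (the caller flags the curve
#'   as `efficiency_failed`).
#' @export
exponential_window <- function(cq, x_sdm, n_cycles, min_points = 4) {
  stopifnot(min_points >= 4)
  if (!(cq < x_sdm) || x_sdm > n_cycles) return(NULL)
  hi <- floor(x_sdm)
  lo <- min(ceiling(cq), hi)
  lo <- max(lo, 1)
  while (hi - lo + 1 < min_points && lo > 1) lo <- lo - 1
  if (hi - lo + 1 < min_points) return(NULL)
  seq.int(lo, hi)
}

#' Per-reaction amplification efficiency from the exponential phase
#'
#' Fits the three-parameter simple exponential model
#' \eqn{F_n = c + \alpha E^n} to the raw fluorescence over the
#' exponential-phase window by nonlinear least squares. `E` is the
#' per-cycle fold-increase of product (2 = perfect doubling). The constant
#' term is a free fitted offset, recorded for transparency.
#'
#' Estimates that diverge or land at the efficiency bounds are failures
#' (returned as `NULL`), never clipped, so they cannot bias a gene's mean
#' efficiency.
#'
#' @param curve Data frame with `cycle` and `fluorescence` for one well.
#' @param window Integer cycles to fit over (from [exponential_window()]);
#'   at least 4 points.
#' @param e_bounds Length-2 numeric, the admissible open interval for `E`
#'   (default `c(1, 3)`).
#' @return A list with `offset`, `alpha`, `e`, `window_cycles`, `rss`, or
#'   `NULL` on failure.
#' @details Starting values come from a log-linear regression after shifting
#'   the window below its minimum; Levenberg-Marquardt then refines all
#'   three parameters. On a short window the RSS surface is shallow, and this
#'   good-start local fit behaves better than exhaustive global optimization,
#'   which chases the mismatch between the idealized exponential and a
#'   gently saturating signal.
#' @export
fit_individual_efficiency <- function(curve, window, e_bounds = c(1, 3)) {
  if (is.null(window) || length(window) < 4) return(NULL)
  idx <- match(window, curve$cycle)
  if (anyNA(idx)) return(NULL)
  n <- as.numeric(window)
  f <- as.numeric(curve$fluorescence[idx])
  if (diff(range(f)) <= 0) return(NULL)

  # log-linear starting values after shifting below the window minimum
  c0 <- min(f) - 0.1 * diff(range(f))
  sl <- lm(log(f - c0) ~ n)
  e0 <- min(max(exp(coef(sl)[[2]]), e_bounds[1] + 0.05), e_bounds[2] - 0.1)
  a0 <- exp(coef(sl)[[1]])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ cc + aa * ee^n,
      data = data.frame(n = n, f = f),
      start = list(cc = c0, aa = a0, ee = e0),
      lower = c(cc = -Inf, aa = 1e-300, ee = e_bounds[1]),
      upper = c(cc = Inf, aa = Inf, ee = e_bounds[2]),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  eps <- 1e-6
  if (p[["ee"]] <= e_bounds[1] + eps || p[["ee"]] >= e_bounds[2] - eps) return(NULL)
  list(offset = p[["cc"]], alpha = p[["aa"]], e = p[["ee"]],
       window_cycles = window, rss = deviance(fit))
}

#' Gene-level mean amplification efficiency
#'
#' Averages the individual efficiencies of all usable reactions of one gene
#' (all concentrations and replicates); reactions whose efficiency fit failed
#' are excluded.
#'
#' @param e_individual Numeric vector of per-reaction efficiencies, `NA` for
#'   failed reactions.
#' @return Arithmetic mean efficiency, or `NA` when no reaction is usable.
#' @export
group_mean_efficiency <- function(e_individual) {
  ok <- e_individual[!is.na(e_individual)]
  if (length(ok) == 0) return(NA_real_)
  mean(ok)
}

#' Initial target quantity from quantification cycle and mean efficiency
#'
#' \deqn{F_0 = E_{mean}^{-C_q}}
#' the starting amount expressed on the fluorescence-derived scale; lower
#' quantification cycles mean more starting template.
#'
#' @param cq Quantification cycle (finite scalar or vector).
#' @param e_mean Mean efficiency, `> 1`.
#' @return `e_mean^(-cq)`.
#' @export
initial_target_quantity <- function(cq, e_mean) {
  if (any(!is.na(e_mean) & e_mean <= 1)) {
    abort("`e_mean` must exceed 1.", class = "cqman_domain_error")
  }
  e_mean^(-cq)
}

quantify_one_curve <- function(curve, min_points, e_bounds, tol, max_iter,
                               amplitude_floor) {
  base <- tibble(
    y0 = NA_real_, ymax = NA_real_, b = NA_real_, x0 = NA_real_,
    rss = NA_real_, x_sdm = NA_real_, fq = NA_real_, cq = NA_real_,
    e_individual = NA_real_, status = "no_amplification"
  )
  fit <- fit_gompertz(curve, tol = tol, max_iter = max_iter,
                      amplitude_floor = amplitude_floor)
  if (!fit$converged) return(base)

  sdm <- sdm_location(fit)
  fq <- quantification_threshold(fit, sdm)
  cq <- quantification_cycle(fit, fq)
  out <- base
  out$y0 <- fit$y0; out$ymax <- fit$ymax; out$b <- fit$b; out$x0 <- fit$x0
  out$rss <- fit$rss; out$x_sdm <- sdm$x_sdm; out$fq <- fq; out$cq <- cq

  win <- exponential_window(cq, sdm$x_sdm, n_cycles = max(curve$cycle),
                            min_points = min_points)
  eff <- fit_individual_efficiency(curve, win, e_bounds = e_bounds)
  if (is.null(eff)) {
    out$status <- "efficiency_failed"
  } else {
    out$e_individual <- eff$e
    out$status <- "ok"
  }
  out
}

#' Analyze a plate of amplification curves
#'
#' The full per-well quantification pipeline: Gompertz fit of the raw
#' fluorescence, analytic second-derivative maximum, midpoint quantification
#' threshold and cycle, exponential-window efficiency fit; then per gene the
#' mean efficiency over all usable reactions; finally per well the initial
#' target quantity \eqn{F_0 = E_{mean}^{-C_q}}. Wells that fail any stage
#' carry a non-`"ok"` status and propagate no further; they never abort the
#' plate. The pipeline is deterministic.
#'
#' @param plate Data frame in long format with columns `well`, `gene`,
#'   `cycle`, `fluorescence` and optionally `sample`, `concentration` (as
#'   produced by [read_amplification_csv()] or [simulate_dilution_plate()]).
#' @param min_points Minimum cycles in the efficiency window.
#' @param e_bounds Admissible open interval for individual efficiency.
#' @param tol,max_iter,amplitude_floor Passed to [fit_gompertz()].
#' @return A tibble with one row per well: `well`, `gene`, `sample`,
#'   `concentration`, the fit parameters `y0`, `ymax`, `b`, `x0`, `rss`,
#'   `x_sdm`, `fq`, `cq`, `e_individual`, `e_mean`, `f0`, `status`.
#' @examples
#' plate <- simulate_dilution_plate(levels = c(15000, 1500, 150),
#'                                  replicates = 2, genes = 1,
#'                                  base_config = sim_config(seed = 7))
#' analyze_plate(plate$curves)
#' @export
analyze_plate <- function(plate, min_points = 4, e_bounds = c(1, 3),
                          tol = 1e-10, max_iter = 200, amplitude_floor = 5) {
  plate <- validate_plate(plate)
  anno <- plate |>
    group_by(.data$well) |>
    summarise(gene = first(.data$gene), sample = first(.data$sample),
              concentration = first(.data$concentration), .groups = "drop")

  per_curve <- plate |>
    group_by(.data$well) |>
    dplyr::group_modify(function(df, key) {
      quantify_one_curve(df, min_points, e_bounds, tol, max_iter, amplitude_floor)
    }) |>
    ungroup()

  res <- left_join(anno, per_curve, by = "well") |>
    group_by(.data$gene) |>
    mutate(e_mean = group_mean_efficiency(.data$e_individual)) |>
    ungroup() |>
    mutate(f0 = ifelse(.data$status == "ok" & !is.na(.data$e_mean),
                       .data$e_mean^(-.data$cq), NA_real_),
           e_mean = ifelse(.data$status == "ok", .data$e_mean, NA_real_))
  res[order(match(res$well, unique(plate$well))), ] |>
    select("well", "gene", "sample", "concentration", "y0", "ymax", "b", "x0",
           "rss", "x_sdm", "fq", "cq", "e_individual", "e_mean", "f0", "status")
}
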