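#' Evaluate the modified Gompertz amplification model
#'
#' The four-parameter sigmoid used to describe a qPCR amplification curve:
#' \deqn{y(x) = y_0 + (y_{max} - y_0)\, e^{-e^{-(x - x_0)/b}}}
#' where `y0` is the baseline fluorescence, `ymax` the plateau fluorescence,
#' `x0` the inflection cycle and `b > 0` the shape (steepness) parameter in
#' cycles. The curve rises from `y0` (as \eqn{x \to -\infty}) to `ymax`
#' (as \eqn{x \to +\infty}).
#'
#' @param fit A `gompertz_fit` object from [fit_gompertz()], or any list with
#'   numeric elements `y0`, `ymax`, `b`, `x0`.
#' @param x Numeric vector of cycle positions (fractional cycles allowed).
#' @return Numeric vector of model fluorescence values, same length as `x`.
#' @examples
#' gompertz_value(list(y0 = 0, ymax = 1, b = 1, x0 = 0), 0)  # exp(-1)
#' @export
gompertz_value <- function(fit, x) {
  if (!is.numeric(fit$b) || fit$b <= 0) {
    abort("`b` must be a positive shape parameter.", class = "cqman_parameter_error")
  }
  fit$y0 + (fit$ymax - fit$y0) * exp(-exp(-(x - fit$x0) / fit$b))
}

# Deterministic derivative-free starting values for a sigmoid rise.
# y0: mean of 3 lowest observations; ymax: max; x0: first upward crossing of
# the half-amplitude level; b: quarter-to-three-quarter rise span / 2.
gompertz_start <- function(cycle, fluor) {
  y0 <- mean(sort(fluor)[1:3])
  ymax <- max(fluor)
  amp <- ymax - y0
  first_above <- function(level) {
    i <- which(fluor >= level)[1]
    if (is.na(i)) return(max(cycle))
    cycle[i]
  }
  x0 <- first_above(y0 + amp / 2)
  b <- max((first_above(y0 + 0.75 * amp) - first_above(y0 + 0.25 * amp)) / 2, 0.5)
  list(y0 = y0, ymax = ymax, b = b, x0 = x0)
}

#' Fit the Gompertz model to one amplification curve
#'
#' Fits the four-parameter modified Gompertz model to raw per-cycle
#' fluorescence by Levenberg-Marquardt least squares. Fitting always uses raw
#' fluorescence; smoothed signal (see [smooth_for_display()]) is never an
#' acceptable input because smoothing biases downstream quantification.
#'
#' A curve is flagged as showing no amplification (rather than raising an
#' error) when the optimizer fails to converge or when the fitted amplitude
#' `ymax - y0` falls below `amplitude_floor` times the standard deviation of
#' the residuals over the first five cycles -- the criterion that rejects
#' no-template-control wells and other flat traces.
#'
#' @param curve Data frame with numeric columns `cycle` (consecutive integers
#'   from 1) and `fluorescence`; one well.
#' @param tol Convergence tolerance on the relative reduction of the residual
#'   sum of squares.
#' @param max_iter Maximum number of Levenberg-Marquardt iterations.
#' @param amplitude_floor Multiplier on the early-cycle residual noise below
#'   which the fitted amplitude is declared non-amplifying.
#' @return An object of class `gompertz_fit`: a list with elements `y0`,
#'   `ymax`, `b`, `x0`, `rss`, `n_iter`, `converged`, `status`
#'   (`"ok"` or `"no_amplification"`) and `data` (the input curve).
#' @seealso [sdm_location()], [quantification_cycle()], [analyze_plate()]
#' @export
fit_gompertz <- function(curve, tol = 1e-10, max_iter = 200, amplitude_floor = 5) {
  stopifnot(is.data.frame(curve), all(c("cycle", "fluorescence") %in% names(curve)))
  cyc <- as.numeric(curve$cycle)
  flr <- as.numeric(curve$fluorescence)

  start <- gompertz_start(cyc, flr)
  failed <- structure(
    list(y0 = NA_real_, ymax = NA_real_, b = NA_real_, x0 = NA_real_,
         rss = NA_real_, n_iter = 0L, converged = FALSE,
         status = "no_amplification", data = tibble(cycle = cyc, fluorescence = flr)),
    class = "gompertz_fit"
  )

  fit <- tryCatch(
    minpack.lm::nlsLM(
      fluorescence ~ y0 + (ymax - y0) * exp(-exp(-(cycle - x0) / b)),
      data = data.frame(cycle = cyc, fluorescence = flr),
      start = start,
      lower = c(y0 = -Inf, ymax = -Inf, b = 1e-3, x0 = -Inf),
      control = minpack.lm::nls.lm.control(ftol = tol, maxiter = max_iter)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)

  p <- as.list(coef(fit))
  res <- flr - gompertz_value(p, cyc)
  early_sd <- max(sd(res[1:5]), 1e-12)
  # amplitude actually expressed within the recorded cycles: an extrapolated
  # sigmoid whose rise falls outside [1, n] is not amplification
  rise <- gompertz_value(p, max(cyc)) - gompertz_value(p, min(cyc))
  conv <- isTRUE(fit$convInfo$isConv)
  if (!conv || rise < amplitude_floor * early_sd) return(failed)

  structure(
    list(y0 = p$y0, ymax = p$ymax, b = p$b, x0 = p$x0,
         rss = deviance(fit), n_iter = fit$convInfo$finIter,
         converged = TRUE, status = "ok",
         data = tibble(cycle = cyc, fluorescence = flr)),
    class = "gompertz_fit"
  )
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("<gompertz_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf("(%s)\n", x$status))
  if (x$converged) {
    cat(sprintf("  y0 = %.6g  ymax = %.6g  b = %.6g  x0 = %.6g\n",
                x$y0, x$ymax, x$b, x$x0))
    cat(sprintf("  rss = %.4g after %d iterations\n", x$rss, x$n_iter))
  }
  invisible(x)
}

#' Locate the second-derivative maximum of a fitted curve
#'
#' The cycle at which the second derivative of the Gompertz curve peaks marks
#' the end of the exponential phase. Writing the model as
#' \eqn{y_0 + A\,e^{-u}} with \eqn{u = e^{-(x-x_0)/b}}, the second derivative
#' peaks where \eqn{u^2 - 3u + 1 = 0}; its pre-inflection root is
#' \eqn{u^* = (3+\sqrt5)/2}, giving the exact location
#' \deqn{x_{SDM} = x_0 - b \ln u^*, \qquad
#'       F_{SDM} = y_0 + (y_{max}-y_0)\,e^{-u^*}.}
#' The fluorescence at the SDM therefore always sits at the fixed fraction
#' \eqn{e^{-u^*} \approx 0.0729} of the amplitude, regardless of parameters.
#'
#' @param fit A converged `gompertz_fit`.
#' @return A one-row tibble with columns `x_sdm` and `f_sdm`.
#' @export
sdm_location <- function(fit) {
  if (!isTRUE(fit$converged)) {
    abort("sdm_location() requires a converged fit.", class = "cqman_state_error")
  }
  tibble(
    x_sdm = fit$x0 - fit$b * log(.u_star),
    f_sdm = fit$y0 + (fit$ymax - fit$y0) * exp(-.u_star)
  )
}
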