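#' Rank synthesis across indicators with a Friedman test
#'
#' Ranks competing curve-analysis methods within each performance indicator
#' (ascending: all indicators are lower-is-better; ties get average ranks),
#' averages ranks per method, and tests for consistent differences among
#' methods with the Friedman statistic, treating indicators as blocks and
#' methods as treatments:
#' \deqn{\chi^2 = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)}
#' with the standard tie correction, referred to the \eqn{\chi^2_{k-1}}
#' distribution. A table in which all methods tie on every indicator has
#' statistic 0.
#'
#' @param indicator_table Data frame whose first column (`method`) names the
#'   methods and whose remaining numeric columns are indicators.
#' @param directions Optional character vector (one per indicator column) of
#'   `"lower_better"` / `"higher_better"`; higher-is-better columns are
#'   ranked descending. Default: all lower-is-better.
#' @return A list of class `rank_synthesis` with `ranks` (tibble of per-
#'   indicator ranks and `mean_rank` per method, sorted best first),
#'   `statistic`, `df`, `p_value`, `n_blocks`, `n_methods`.
#' @examples
#' tab <- data.frame(method = c("A", "B", "C"),
#'                   re = c(0.1, 0.3, 0.2), cv = c(5, 12, 8))
#' rank_synthesis(tab)
#' @export
rank_synthesis <- function(indicator_table, directions = NULL) {
  df <- as.data.frame(indicator_table)
  methods <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  if (nrow(vals) < 2 || ncol(vals) < 2) {
    abort("Need at least 2 methods and 2 indicators.",
          class = "cqman_validation_error")
  }
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("All indicator columns must be numeric.",
          class = "cqman_validation_error")
  }
  if (is.null(directions)) directions <- rep("lower_better", ncol(vals))
  stopifnot(length(directions) == ncol(vals),
            all(directions %in% c("lower_better", "higher_better")))

  # rank matrix: methods x indicators, average ranks for ties
  rmat <- vapply(seq_along(vals), function(j) {
    v <- vals[[j]]
    if (directions[j] == "higher_better") v <- -v
    rank(v, ties.method = "average")
  }, numeric(nrow(vals)))
  colnames(rmat) <- names(vals)

  k <- length(methods)          # treatments
  n <- ncol(rmat)               # blocks = indicators
  rj <- rowSums(rmat)           # rank sum per method across blocks

  # tie correction: sum over blocks of (t^3 - t) over tie groups
  ties <- sum(apply(rmat, 2, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  num <- 12 * sum((rj - n * (k + 1) / 2)^2)
  statistic <- if (denom <= 0) 0 else num / denom
  p <- pchisq(statistic, df = k - 1, lower.tail = FALSE)

  ranks <- as_tibble(rmat) |>
    mutate(method = methods, .before = 1) |>
    mutate(mean_rank = rowMeans(rmat)) |>
    arrange(.data$mean_rank)

  structure(list(ranks = ranks, statistic = statistic, df = k - 1,
                 p_value = p, n_blocks = n, n_methods = k),
            class = "rank_synthesis")
}

#' @export
print.rank_synthesis <- function(x, ...) {
  cat("<rank_synthesis>", x$n_methods, "methods over", x$n_blocks,
      "indicators\n")
  print(x$ranks)
  cat(sprintf("Friedman chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
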