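test_that("normalization centres the top replicate group at exactly 1", {
  tab <- tibble::tibble(gene = "g1",
                        concentration = rep(c(100, 10), each = 3),
                        f0 = c(2e-6, 2e-6, 2e-6, 1e-7, 2e-7, 3e-7))
  norm <- normalize_f0(tab)
  expect_equal(norm$f0_norm[1:3], c(1, 1, 1))
  expect_equal(norm$nc, rep(c(1, 0.1), each = 3))
  tab2 <- tibble::tibble(gene = "g1", concentration = c(100, 100, 10),
                         f0 = c(1e-6, 3e-6, 1e-7))
  expect_equal(normalize_f0(tab2)$f0_norm[1:2], c(0.5, 1.5))
  # the standard 5-level 10-fold ladder
  tab3 <- perfect_f0_table(genes = 1)
  expect_equal(sort(unique(normalize_f0(tab3)$nc)),
               c(1e-4, 1e-3, 1e-2, 1e-1, 1))
})

test_that("per-gene rescaling of raw F0 changes no indicator", {
  tab <- perfect_f0_table(genes = 2)
  tab$f0 <- tab$f0 * (1 + 0.1 * sin(seq_len(nrow(tab))))  # imperfect data
  scaled <- tab
  scaled$f0 <- scaled$f0 * ifelse(scaled$gene == "g1", 5e3, 0.02)
  for (f in list(function(x) bias_ratio(x, 1e4), bias_slope, relative_error,
                 coefficient_of_variation, precision_within_group,
                 resolution_fold)) {
    expect_equal(f(normalize_f0(scaled)), f(normalize_f0(tab)),
                 tolerance = 1e-10)
  }
})

test_that("indicators are permutation-invariant to well order", {
  tab <- perfect_f0_table(genes = 2)
  tab$f0 <- tab$f0 * (1 + 0.05 * cos(seq_len(nrow(tab))))
  shuf <- withr::with_seed(5, tab[sample(nrow(tab)), ])
  expect_equal(glance(indicator_report(shuf)),
               glance(indicator_report(tab)), tolerance = 1e-12)
})

test_that("bias_ratio measures deviation of the extreme-group ratio", {
  norm <- normalize_f0(perfect_f0_table(genes = 3))
  expect_equal(bias_ratio(norm, 1e4, "high_over_low"), 0)
  # 4-level series read low-over-high
  tab4 <- perfect_f0_table(genes = 1, levels = c(15000, 1500, 150, 15))
  expect_equal(bias_ratio(normalize_f0(tab4), 0.001, "low_over_high"), 0)
  # a gene with ratio 12000 deviates by 2000
  skew <- perfect_f0_table(genes = 1)
  skew$f0[skew$concentration == 15] <- skew$f0[skew$concentration == 15] / 1.2
  expect_equal(bias_ratio(normalize_f0(skew), 1e4), 2000, tolerance = 1e-9)
})

test_that("bias_slope measures deviation of the log-log slope from 1", {
  norm <- normalize_f0(perfect_f0_table(genes = 2))
  expect_equal(bias_slope(norm), 0, tolerance = 1e-12)
  pow <- perfect_f0_table(genes = 2)
  pow$f0 <- (pow$f0)^1.1
  expect_equal(bias_slope(normalize_f0(pow)), 0.1, tolerance = 1e-9)
  # constant multiple is absorbed by the intercept (and by normalization)
  mult <- perfect_f0_table(genes = 1)
  mult$f0 <- 3.14 * mult$f0
  expect_equal(bias_slope(normalize_f0(mult)), 0, tolerance = 1e-12)
})

test_that("relative error aggregates mean absolute deviation", {
  norm <- normalize_f0(perfect_f0_table(genes = 1))
  expect_equal(relative_error(norm), 0)
  # +20% and -20% average to 0.2 in absolute value
  tab <- tibble::tibble(gene = "g", concentration = c(10, 10, 1, 1),
                        f0 = c(1.2, 0.8, 0.12, 0.08))
  norm2 <- normalize_f0(tab)
  expect_equal(relative_error(norm2), 0.2, tolerance = 1e-12)
})

test_that("coefficient of variation and precision follow sample statistics", {
  tab <- tibble::tibble(gene = "g", concentration = rep(c(10, 1), each = 3),
                        f0 = c(2, 2, 2, 1, 2, 3))
  norm <- normalize_f0(tab)
  # top group {2,2,2}: CV 0; bottom {1,2,3}: sd 1, mean 2 -> 50%; average 25%
  expect_equal(coefficient_of_variation(norm), 25, tolerance = 1e-12)
  tab2 <- tibble::tibble(gene = "g", concentration = rep(c(10, 1), each = 3),
                         f0 = c(1, 1, 1, 0.9, 1.0, 1.1))
  norm2 <- normalize_f0(tab2)
  # variances {0, 0.01} average to 0.005
  expect_equal(precision_within_group(norm2), 0.005, tolerance = 1e-12)
})

test_that("resolution fold is 1 for perfect data and matches the closed form", {
  norm <- normalize_f0(perfect_f0_table(genes = 1))
  expect_equal(resolution_fold(norm), 1, tolerance = 1e-9)

  # closed-form prediction-interval oracle: log-linear data with known
  # residuals; h = t * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)
  levels <- c(150000, 15000, 1500, 150, 15)
  tab <- perfect_f0_table(genes = 1, levels = levels)
  resid_pattern <- rep(c(-0.1, 0, 0.1), times = 5)     # in log10 F0 units
  tab$f0 <- tab$f0 * 10^resid_pattern
  norm2 <- normalize_f0(tab)
  fold <- resolution_fold(norm2)

  x <- log10(norm2$f0_norm); y <- log10(norm2$nc)
  m <- lm(y ~ x)
  s <- sqrt(sum(m$residuals^2) / (15 - 2))
  xbar <- mean(x); sxx <- sum((x - xbar)^2)
  at <- tapply(x, y, mean)
  hw <- qt(0.975, 13) * s * sqrt(1 + 1 / 15 + (at - xbar)^2 / sxx)
  expect_equal(fold, exp(mean(log(10^hw))), tolerance = 1e-9)
  expect_gt(fold, 1)

  # doubling residual spread strictly inflates the fold
  tab3 <- perfect_f0_table(genes = 1, levels = levels)
  tab3$f0 <- tab3$f0 * 10^(2 * resid_pattern)
  expect_gt(resolution_fold(normalize_f0(tab3)), fold)
})

test_that("resolution prediction interval has the stated width over seeds", {
  # simulated log-normal scatter around a perfect ladder; compare the mean
  # fold with the closed-form expectation for s = 0.1 at n = 15
  levels <- c(150000, 15000, 1500, 150, 15)
  folds <- sapply(1:200, function(s) {
    tab <- perfect_f0_table(genes = 1, levels = levels)
    tab$f0 <- tab$f0 * 10^withr::with_seed(s, rnorm(15, 0, 0.1))
    resolution_fold(normalize_f0(tab))
  })
  # expected half-width with the 5-level ladder geometry: level means sit at
  # (x - xbar)^2 = {4,1,0,1,4}, Sxx ~ 3*10, so the mean leverage term is 1/15
  h_exp <- qt(0.975, 13) * 0.1 * sqrt(1 + 1 / 15 + 1 / 15)
  expect_equal(median(folds), 10^h_exp, tolerance = 0.05)
})

test_that("indicator_report bundles all six indicators with per-gene detail", {
  rep_perfect <- indicator_report(perfect_f0_table(genes = 3))
  gl <- glance(rep_perfect)
  expect_equal(gl$bias_ratio_dev, 0)
  expect_equal(gl$bias_slope_dev, 0, tolerance = 1e-12)
  expect_equal(gl$mean_relative_error, 0)
  expect_equal(gl$mean_cv, 0)
  expect_equal(gl$mean_precision, 0)
  expect_equal(gl$resolution_fold, 1, tolerance = 1e-9)
  expect_equal(nrow(tidy(rep_perfect)), 3)
  # JSON export round-trips the scalars
  path <- withr::local_tempfile(fileext = ".json")
  write_indicator_report(rep_perfect, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$resolution_fold, 1, tolerance = 1e-9)
})
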