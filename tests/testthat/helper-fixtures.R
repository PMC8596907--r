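# Shared fixtures, built in code.

# noiseless curve sampled from the Gompertz model itself (for fit-recovery
# tests where the generating model must match the fitted model)
gompertz_curve <- function(y0 = 0.05, ymax = 1.05, b = 1.5, x0 = 25,
                           n_cycles = 40) {
  pars <- list(y0 = y0, ymax = ymax, b = b, x0 = x0)
  tibble::tibble(cycle = seq_len(n_cycles),
                 fluorescence = gompertz_value(pars, seq_len(n_cycles)))
}

# perfectly calibrated dilution table: F0 equals the normalized concentration
perfect_f0_table <- function(genes = 2, levels = c(150000, 15000, 1500, 150, 15),
                             replicates = 3) {
  tidyr::expand_grid(gene = sprintf("g%d", seq_len(genes)),
                     concentration = levels,
                     rep = seq_len(replicates)) |>
    dplyr::mutate(f0 = concentration / max(levels))
}

# brute-force grid maximizer of the numeric second difference of the model;
# independent of the closed form under test
grid_sdm <- function(pars, coarse_step = 0.01, fine_step = 1e-4, d = 1e-3) {
  second_diff <- function(x) {
    (gompertz_value(pars, x + d) - 2 * gompertz_value(pars, x) +
       gompertz_value(pars, x - d)) / d^2
  }
  xs <- seq(pars$x0 - 6 * pars$b, pars$x0 + 2 * pars$b, by = coarse_step)
  x1 <- xs[which.max(second_diff(xs))]
  xf <- seq(x1 - 2 * coarse_step, x1 + 2 * coarse_step, by = fine_step)
  xf[which.max(second_diff(xf))]
}

# standard simulator settings used across tests (the package defaults, with a
# fixed seed)
test_config <- function(seed = 42, ...) sim_config(seed = seed, ...)
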