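#' Simulation settings for one amplification reaction
#'
#' Mechanistic per-cycle kinetics: product copies follow
#' \eqn{N_n = N_{n-1} E_n} with a per-cycle efficiency that decays as
#' reagents become limiting,
#' \eqn{E_n = 1 + (E - 1) / (1 + (N_{n-1}/K)^h)},
#' and observed fluorescence
#' \eqn{F_n = baseline + drift\,n + scale\,N_n + \epsilon_n},
#' \eqn{\epsilon_n \sim N(0, \sigma^2)}. Curves are deliberately NOT drawn
#' from the Gompertz model, so sigmoid fitting is exercised under model
#' mismatch, as with instrument data.
#'
#' @param n0 Initial target copies.
#' @param efficiency Per-cycle fold increase `E` before saturation, in (1, 2].
#' @param carrying_capacity Product level `K` (copies) where efficiency
#'   starts to decay.
#' @param hill Sharpness `h` of the efficiency decline.
#' @param fluorescence_scale Fluorescence units per copy; `NULL` (default)
#'   scales the noiseless plateau of this configuration to 1.0 above
#'   baseline, the magnitude of a normalized SYBR trace.
#' @param baseline Background fluorescence.
#' @param baseline_drift Linear baseline drift per cycle.
#' @param noise_sd Additive Gaussian noise SD (fluorescence units).
#' @param n_cycles Number of thermal cycles (>= 10).
#' @param seed Integer seed; identical configurations give bit-identical
#'   curves.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n0 = 10000, efficiency = 1.85, carrying_capacity = 3e10,
                       hill = 1.67, fluorescence_scale = NULL, baseline = 0.05,
                       baseline_drift = 0, noise_sd = 0, n_cycles = 40,
                       seed = 1) {
  stopifnot(n0 > 0, efficiency > 1, efficiency <= 2, carrying_capacity > 0,
            hill > 0, noise_sd >= 0, n_cycles >= 10)
  structure(list(n0 = n0, efficiency = efficiency,
                 carrying_capacity = carrying_capacity, hill = hill,
                 fluorescence_scale = fluorescence_scale, baseline = baseline,
                 baseline_drift = baseline_drift, noise_sd = noise_sd,
                 n_cycles = as.integer(n_cycles), seed = as.integer(seed)),
            class = "sim_config")
}

# copy-number trajectory N_1..N_n (no fluorescence mapping, no noise)
sim_copies <- function(config) {
  n <- config$n_cycles
  out <- numeric(n)
  prev <- config$n0
  for (i in seq_len(n)) {
    e_i <- 1 + (config$efficiency - 1) /
      (1 + (prev / config$carrying_capacity)^config$hill)
    prev <- prev * e_i
    out[i] <- prev
  }
  out
}

#' Simulate one amplification curve
#'
#' @param config A [sim_config()].
#' @param well,gene,sample,concentration Annotation fields for the returned
#'   curve; `concentration` defaults to the configured `n0`.
#' @return A long-format tibble (`well,gene,sample,concentration,cycle,
#'   fluorescence`) for one well.
#' @examples
#' curve <- simulate_curve(sim_config(n0 = 1500, noise_sd = 0.01, seed = 3))
#' @export
simulate_curve <- function(config, well = "W1", gene = "gene1",
                           sample = "synthetic", concentration = config$n0) {
  copies <- sim_copies(config)
  scale <- config$fluorescence_scale
  if (is.null(scale)) {
    # plateau of the noiseless trajectory maps to 1.0 above baseline
    scale <- 1 / max(copies)
  }
  n <- config$n_cycles
  noise <- if (config$noise_sd > 0) {
    withr::with_seed(config$seed, rnorm(n, 0, config$noise_sd))
  } else rep(0, n)
  fl <- config$baseline + config$baseline_drift * seq_len(n) +
    scale * copies + noise
  tibble(well = well, gene = gene, sample = sample,
         concentration = concentration, cycle = seq_len(n), fluorescence = fl)
}

#' Simulate a dilution-series plate with ground truth
#'
#' One curve per gene x concentration level x replicate, emulating the
#' standard dilution-series validation design (e.g. a 5-point 10-fold series
#' from 150,000 down to 15 copies in triplicate across 20 amplicons, or a
#' 4-point series with many replicates of a single amplicon). Per-gene
#' kinetic parameters (true efficiency, baseline) are jittered
#' deterministically from the seed so amplicons differ as they do on a real
#' plate; the fluorescence scale is fixed per gene so all of a gene's wells
#' share one plateau.
#'
#' @param levels Descending positive concentrations (copies).
#' @param replicates Replicates per level.
#' @param genes Number of amplicons.
#' @param base_config [sim_config()] template; its `n0` is overridden by
#'   `levels` and its seed drives all jitter and noise.
#' @param gene_efficiency_sd SD of the per-gene jitter on true efficiency
#'   (truncated to (1.6, 2]); the small default reflects the tight
#'   efficiency spread of an optimized assay panel.
#' @return A list with `curves` (long tibble over all wells) and `truth`
#'   (tibble `well,gene,true_n0,true_e`).
#' @export
simulate_dilution_plate <- function(levels, replicates, genes,
                                    base_config = sim_config(),
                                    gene_efficiency_sd = 0.01) {
  stopifnot(all(diff(levels) < 0), replicates >= 1, genes >= 1)
  gene_ids <- sprintf("gene%02d", seq_len(genes))

  gene_par <- withr::with_seed(base_config$seed, {
    tibble(
      gene = gene_ids,
      true_e = pmin(pmax(rnorm(genes, base_config$efficiency,
                               gene_efficiency_sd), 1.6), 2),
      baseline = base_config$baseline * runif(genes, 0.8, 1.2)
    )
  })

  grid <- tidyr::expand_grid(gene = gene_ids,
                             level = seq_along(levels),
                             rep = seq_len(replicates)) |>
    mutate(n0 = levels[.data$level],
           well = sprintf("%s_L%d_R%d", .data$gene, .data$level, .data$rep),
           well_seed = (base_config$seed + 7919L * dplyr::row_number()) %% .Machine$integer.max) |>
    left_join(gene_par, by = "gene")

  # fixed per-gene fluorescence scale: plateau of the top level maps to ~1
  grid <- grid |>
    group_by(.data$gene) |>
    mutate(scale = {
      cfg <- sim_config(n0 = max(.data$n0), efficiency = first(.data$true_e),
                        carrying_capacity = base_config$carrying_capacity,
                        hill = base_config$hill,
                        n_cycles = base_config$n_cycles, seed = 1L)
      1 / max(sim_copies(cfg))
    }) |>
    ungroup()

  curves <- purrr::pmap(grid, function(gene, level, rep, n0, well, well_seed,
                                       true_e, baseline, scale) {
    cfg <- sim_config(n0 = n0, efficiency = true_e,
                      carrying_capacity = base_config$carrying_capacity,
                      hill = base_config$hill, fluorescence_scale = scale,
                      baseline = baseline,
                      baseline_drift = base_config$baseline_drift,
                      noise_sd = base_config$noise_sd,
                      n_cycles = base_config$n_cycles, seed = well_seed)
    simulate_curve(cfg, well = well, gene = gene, sample = "dilution_series",
                   concentration = n0)
  }) |> bind_rows()

  list(curves = curves,
       truth = tibble(well = grid$well, gene = grid$gene,
                      true_n0 = grid$n0, true_e = grid$true_e))
}

#' Simulate no-template-control wells
#'
#' Baseline plus drift plus noise only: no exponential component.
#' [analyze_plate()] must flag every such well as `no_amplification`.
#'
#' @param base_config [sim_config()] supplying baseline, drift, noise and
#'   cycle count.
#' @param n_wells Number of NTC wells.
#' @return Long-format tibble of NTC curves.
#' @export
simulate_ntc <- function(base_config = sim_config(noise_sd = 0.01),
                         n_wells = 3) {
  stopifnot(n_wells >= 1)
  purrr::map(seq_len(n_wells), function(i) {
    n <- base_config$n_cycles
    seed_i <- (base_config$seed + 104729L * i) %% .Machine$integer.max
    noise <- if (base_config$noise_sd > 0) {
      withr::with_seed(seed_i, rnorm(n, 0, base_config$noise_sd))
    } else rep(0, n)
    tibble(well = sprintf("NTC%d", i), gene = "NTC", sample = "ntc",
           concentration = NA_real_, cycle = seq_len(n),
           fluorescence = base_config$baseline +
             base_config$baseline_drift * seq_len(n) + noise)
  }) |> bind_rows()
}
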