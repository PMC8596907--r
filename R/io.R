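#' Validate a long-format plate of amplification curves
#'
#' Checks the invariants every downstream operation relies on: each well's
#' cycles are consecutive integers starting at 1, at least 10 cycles per well
#' (fewer cannot support baseline + exponential + plateau fitting), finite
#' numeric fluorescence, and well identifiers consistent with a single gene /
#' sample / concentration annotation.
#'
#' @param plate Data frame with columns `well`, `gene`, `cycle`,
#'   `fluorescence`; `sample` and `concentration` are added (as `NA`) when
#'   missing.
#' @return The validated plate as a tibble, cycles ordered within well.
#' @export
validate_plate <- function(plate) {
  required <- c("well", "gene", "cycle", "fluorescence")
  missing_cols <- setdiff(required, names(plate))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cqman_format_error")
  }
  plate <- as_tibble(plate)
  if (!"sample" %in% names(plate)) plate$sample <- NA_character_
  if (!"concentration" %in% names(plate)) plate$concentration <- NA_real_

  if (!is.numeric(plate$fluorescence)) {
    bad <- which(is.na(suppressWarnings(as.numeric(plate$fluorescence))))[1]
    abort(sprintf("Non-numeric fluorescence at row %d.", bad),
          class = "cqman_parse_error")
  }
  if (any(!is.finite(plate$fluorescence))) {
    abort("Fluorescence values must be finite.", class = "cqman_validation_error")
  }

  plate <- arrange(plate, match(.data$well, unique(.data$well)), .data$cycle)
  for (w in unique(plate$well)) {
    cyc <- plate$cycle[plate$well == w]
    if (length(cyc) < 10) {
      abort(sprintf("Well '%s' has %d cycles; at least 10 are required.",
                    w, length(cyc)),
            class = "cqman_validation_error")
    }
    if (!isTRUE(all(cyc == seq_along(cyc)))) {
      abort(sprintf("Well '%s' does not have consecutive integer cycles starting at 1.", w),
            class = "cqman_validation_error")
    }
  }
  plate
}

#' Read amplification curves from CSV
#'
#' Two dialects are supported. The canonical `long` dialect has columns
#' `well,gene,sample,concentration,cycle,fluorescence`, one row per well and
#' cycle; `concentration` may be empty for wells of unknown input (they are
#' simply excluded from dilution-series indicators). The `wide` dialect has
#' a `Cycle` column plus one fluorescence column per well, with gene / sample
#' / concentration annotations supplied in a sidecar CSV
#' (`well,gene,sample,concentration`).
#'
#' @param path Path to the curves CSV.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param annotations Path to the annotation CSV (wide dialect only).
#' @return A validated long-format tibble of curves (see [validate_plate()]).
#' @export
read_amplification_csv <- function(path, dialect = c("long", "wide"),
                                   annotations = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cqman_io_error")
  }
  if (dialect == "long") {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_guess()))
    required <- c("well", "gene", "sample", "concentration", "cycle", "fluorescence")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("Missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "cqman_format_error")
    }
    if (!is.numeric(df$fluorescence)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$fluorescence))))[1]
      abort(sprintf("Non-numeric fluorescence at row %d of %s.", bad, path),
            class = "cqman_parse_error")
    }
    df$well <- as.character(df$well)
    df$gene <- as.character(df$gene)
    df$sample <- as.character(df$sample)
    df$concentration <- suppressWarnings(as.numeric(df$concentration))
    return(validate_plate(df))
  }

  # wide: Cycle + one column per well, annotations sidecar
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"Cycle" %in% names(df)) {
    abort("Missing required column(s): Cycle", class = "cqman_format_error")
  }
  if (is.null(annotations) || !file.exists(annotations)) {
    abort("Wide dialect requires an `annotations` CSV (well,gene,sample,concentration).",
          class = "cqman_format_error")
  }
  anno <- readr::read_csv(annotations, show_col_types = FALSE)
  required <- c("well", "gene", "sample", "concentration")
  missing_cols <- setdiff(required, names(anno))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s) in annotations: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cqman_format_error")
  }
  long <- tidyr::pivot_longer(df, -"Cycle", names_to = "well",
                              values_to = "fluorescence") |>
    dplyr::rename(cycle = "Cycle") |>
    mutate(well = as.character(.data$well))
  anno <- mutate(anno, well = as.character(.data$well),
                 gene = as.character(.data$gene),
                 sample = as.character(.data$sample),
                 concentration = suppressWarnings(as.numeric(.data$concentration)))
  merged <- left_join(long, anno, by = "well") |>
    select("well", "gene", "sample", "concentration", "cycle", "fluorescence")
  validate_plate(merged)
}

#' Write a long-format curve table to CSV
#'
#' Writes the canonical long dialect so that a plate round-trips through
#' [read_amplification_csv()] unchanged.
#'
#' @param plate Long-format curves tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplification_csv <- function(plate, path) {
  plate <- validate_plate(plate)
  readr::write_csv(plate[, c("well", "gene", "sample", "concentration",
                             "cycle", "fluorescence")], path)
  invisible(path)
}

results_columns <- c("well", "gene", "y0", "ymax", "b", "x0", "x_sdm", "fq",
                     "cq", "e_individual", "e_mean", "f0", "status")

#' Write per-well quantification results to CSV
#'
#' Fixed column order `well,gene,y0,ymax,b,x0,x_sdm,fq,cq,e_individual,
#' e_mean,f0,status`; numeric fields keep full precision; wells that failed
#' carry their status and empty numeric fields.
#'
#' @param results Tibble from [analyze_plate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  missing_cols <- setdiff(results_columns, names(results))
  if (length(missing_cols) > 0) {
    abort(paste0("Results table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cqman_format_error")
  }
  readr::write_csv(results[, results_columns], path, na = "")
  invisible(path)
}

#' Read back a quantification results CSV
#'
#' @param path Path written by [write_results()].
#' @return Tibble with the fixed results schema.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cqman_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          well = readr::col_character(),
                          gene = readr::col_character(),
                          status = readr::col_character(),
                          .default = readr::col_double()
                        ))
  missing_cols <- setdiff(results_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cqman_format_error")
  }
  df
}

#' Savitzky-Golay smoothing for display only
#'
#' Polynomial least-squares smoothing of one well's fluorescence trace, for
#' plotting. The smoothed signal is never consumed by any quantification
#' step: fitting, thresholding and efficiency estimation all operate on raw
#' fluorescence, because smoothing biases amplification-curve quantification.
#'
#' @param curve Data frame with `cycle` and `fluorescence` for one well.
#' @param window Odd filter length, at least `order + 2` and at most the
#'   number of cycles.
#' @param order Polynomial order of the filter.
#' @return Numeric vector of smoothed fluorescence, same length as the input.
#' @export
smooth_for_display <- function(curve, window = 5, order = 2) {
  f <- as.numeric(curve$fluorescence)
  if (window %% 2 == 0 || window < order + 2 || window > length(f)) {
    abort("`window` must be odd, >= order + 2 and <= the number of cycles.",
          class = "cqman_parameter_error")
  }
  as.numeric(signal::sgolayfilt(f, p = order, n = window))
}
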