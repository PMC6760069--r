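#' Poisson-corrected mutant concentration (copies/ul)
#'
#' At occupancy p = positives / valid wells, the expected copies per well is
#' the Poisson rate lambda = -ln(1 - p), and the concentration in the
#' reaction mix is lambda / partition_volume, in copies/ul (cpm). At the
#' occupancies seen in practice (p below a few permille) the correction is
#' fractions of a percent; a saturated chip (every valid well positive) has
#' no finite estimate and raises an error.
#'
#' @param summary A `partition_summary` from [call_partitions()].
#' @param spec A [chip_spec()]; defaults to the one carried on `summary`.
#' @return Mutant copies per ul of reaction mix (unrounded).
#' @examples
#' s <- tibble::tibble(n_total = 20000, n_valid = 20000,
#'                     n_positive = 20, qc_pass = TRUE)
#' poisson_cpm(s, chip_spec())  # ~1.334
#' @export
poisson_cpm <- function(summary, spec = NULL) {
  if (is.null(spec)) spec <- attr(summary, "spec", exact = TRUE)
  if (is.null(spec)) {
    stop_input("No chip geometry available; supply `spec`.",
               "mosaicdpcr_input_error")
  }
  if (summary$n_valid <= 0) {
    stop_input("No valid partitions; cannot quantify.", "mosaicdpcr_input_error")
  }
  if (summary$n_positive >= summary$n_valid) {
    stop_input("Chip is saturated (all valid wells positive); no finite estimate.",
               "mosaicdpcr_saturation_error")
  }
  p <- summary$n_positive / summary$n_valid
  lambda <- -log1p(-p)
  lambda / spec$partition_volume
}

#' Absolute quantification: cpm to ng/ul
#'
#' Applies the instrument conversion cpm x 0.0033 ng (mass of one haploid
#' human genome) x 3.34 (dilution factor for 15 ul of sample plus reaction
#' mixture), rounded half-up to two decimals as in the reported tables.
#'
#' @param cpm Mutant copies per ul (vectorised, each element >= 0).
#' @param constants A [quant_constants()].
#' @return ng/ul of mutant DNA, two decimals.
#' @examples
#' absolute_quant(12.11)   # 0.13
#' absolute_quant(17.47)   # 0.19
#' absolute_quant(32.654)  # 0.36
#' @export
absolute_quant <- function(cpm, constants = quant_constants()) {
  if (!is.numeric(cpm) || anyNA(cpm) || any(cpm < 0)) {
    stop_input("`cpm` must be non-negative and non-missing.",
               "mosaicdpcr_domain_error")
  }
  round_half_up(cpm * constants$genome_mass_ng * constants$dilution_factor, 2)
}

#' One-call quantification of a chip
#'
#' Runs [call_partitions()] and [poisson_cpm()] and formats the result the way
#' the per-sample tables report it: cpm to three decimals, ng/ul to two,
#' half-up. A chip failing QC keeps its numbers but is flagged
#' `reportable = FALSE`.
#'
#' @inheritParams call_partitions
#' @param constants A [quant_constants()].
#' @return A one-row tibble: `n_total`, `n_valid`, `n_positive`, `qc_pass`,
#'   `cpm`, `abs_ng_per_ul`, `reportable`.
#' @examples
#' chip <- simulate_chip(sim_params(het_cell_fraction = 0.25, seed = 1))
#' quantify_chip(chip)
#' @export
quantify_chip <- function(chip, policy = qc_policy(),
                          constants = quant_constants(),
                          rfu_threshold = NULL) {
  s <- call_partitions(chip, policy = policy, rfu_threshold = rfu_threshold)
  cpm <- round_half_up(poisson_cpm(s), 3)
  dplyr::mutate(tibble::as_tibble(s),
                cpm = cpm,
                abs_ng_per_ul = absolute_quant(cpm, constants),
                reportable = .data$qc_pass)
}
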