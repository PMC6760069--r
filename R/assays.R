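#' GNAS mutation-detection assay definitions
#'
#' The two FAM-labelled rare-mutation assays targeting the GNAS hotspot codon
#' (historically Arg201, Arg202 under LRG numbering), with the fluorescence
#' thresholds above which a partition is called positive. The pairing between
#' assay id and coding change is fixed: `GNAS_27887_mu` detects c.604C>T
#' (p.Arg202Cys) at RFU > 5000 and `GNAS_27895_mu` detects c.605G>A
#' (p.Arg202His) at RFU > 3000.
#'
#' @return A tibble with columns `assay_id`, `target_variant` and
#'   `rfu_threshold` (relative fluorescence units).
#' @examples
#' gnas_assays()
#' @export
gnas_assays <- function() {
  tibble::tibble(
    assay_id       = c("GNAS_27887_mu", "GNAS_27895_mu"),
    target_variant = c("c.604C>T", "c.605G>A"),
    rfu_threshold  = c(5000, 3000)
  )
}

#' Look up a single assay definition
#'
#' @param assay Assay id (`"GNAS_27887_mu"`, `"GNAS_27895_mu"`) or target
#'   variant (`"c.604C>T"`, `"c.605G>A"`).
#' @return A one-row tibble as in [gnas_assays()].
#' @examples
#' gnas_assay("c.605G>A")
#' @export
gnas_assay <- function(assay) {
  defs <- gnas_assays()
  hit <- defs[defs$assay_id == assay | defs$target_variant == assay, ]
  if (nrow(hit) != 1L) {
    stop_input(sprintf("Unknown assay '%s'; use one of %s.", assay,
                       paste(c(defs$assay_id, defs$target_variant), collapse = ", ")),
               "mosaicdpcr_config_error")
  }
  hit
}

#' Nanowell chip geometry
#'
#' Describes the physical layout of a digital-PCR chip: number of partitions,
#' the volume of a single partition and the reaction volume loaded onto the
#' chip. Defaults match a 20,000-well chip loaded with 15 ul of sample plus
#' reaction mixture; the per-well volume, not reported by the instrument
#' vendor at this precision, defaults to the loaded volume spread evenly over
#' the wells (15/20000 ul).
#'
#' @param n_partitions Number of wells on the chip.
#' @param partition_volume Volume of one well, ul.
#' @param loaded_volume Reaction volume loaded on the chip, ul.
#' @return A one-row tibble of class `chip_spec`.
#' @examples
#' chip_spec()
#' @export
chip_spec <- function(n_partitions = 20000L,
                      partition_volume = 15 / 20000,
                      loaded_volume = 15) {
  check_number(n_partitions, "n_partitions", min = 1)
  check_number(partition_volume, "partition_volume", min = 0, strict_min = TRUE)
  check_number(loaded_volume, "loaded_volume", min = 0, strict_min = TRUE)
  if (n_partitions * partition_volume > loaded_volume + 1e-9) {
    stop_input("Total partition volume exceeds the loaded volume.",
               "mosaicdpcr_config_error")
  }
  out <- tibble::tibble(
    n_partitions = as.integer(n_partitions),
    partition_volume = partition_volume,
    loaded_volume = loaded_volume
  )
  class(out) <- c("chip_spec", class(out))
  out
}

#' Per-chip quality-control policy
#'
#' A chip is reportable only when enough wells pass the per-well quality
#' score. Defaults follow the validated analysis settings: a floor of 10,000
#' quality-passing data points per chip with a per-well quality threshold of
#' 0.6 (wells must score strictly above it).
#'
#' @param min_valid_partitions Minimum number of quality-passing wells for the
#'   chip to pass QC.
#' @param min_quality Per-well quality score that must be strictly exceeded.
#' @return A one-row tibble of class `qc_policy`.
#' @export
qc_policy <- function(min_valid_partitions = 10000L, min_quality = 0.6) {
  check_number(min_valid_partitions, "min_valid_partitions", min = 1)
  check_number(min_quality, "min_quality", min = 0, max = 1)
  out <- tibble::tibble(
    min_valid_partitions = as.integer(min_valid_partitions),
    min_quality = min_quality
  )
  class(out) <- c("qc_policy", class(out))
  out
}

#' Constants of the absolute-quantification formula
#'
#' Converts mutant copies/ul of reaction mix (cpm) to ng/ul of mutant DNA as
#' cpm x 0.0033 ng (mass of one haploid human genome) x 3.34 (dilution factor
#' for 15 ul of sample plus reaction mixture). Both constants are used
#' verbatim as printed; the dilution factor is treated as an opaque
#' instrument constant rather than rederived from volumes.
#'
#' @param genome_mass_ng Mass of one haploid genome, ng.
#' @param dilution_factor Dimensionless dilution factor.
#' @return A one-row tibble of class `quant_constants`.
#' @export
quant_constants <- function(genome_mass_ng = 0.0033, dilution_factor = 3.34) {
  check_number(genome_mass_ng, "genome_mass_ng", min = 0, strict_min = TRUE)
  check_number(dilution_factor, "dilution_factor", min = 0, strict_min = TRUE)
  out <- tibble::tibble(genome_mass_ng = genome_mass_ng,
                        dilution_factor = dilution_factor)
  class(out) <- c("quant_constants", class(out))
  out
}

#' Two-component fluorescence model for simulated wells
#'
#' Wells holding at least one mutant template draw their FAM signal from the
#' positive component, template-free wells from the negative component.
#' Defaults (negative 1000 +/- 400 RFU, positive 8000 +/- 800 RFU) keep both
#' assay thresholds (3000 and 5000 RFU) squarely between the components.
#' `quality_low_fraction` is the fraction of wells whose quality score falls
#' below the 0.6 QC threshold for reasons other than loading failure.
#'
#' @param neg_mean,neg_sd RFU distribution of template-free wells.
#' @param pos_mean,pos_sd RFU distribution of template-bearing wells.
#' @param quality_low_fraction Fraction of wells drawing a sub-threshold
#'   quality score.
#' @return A one-row tibble of class `fluor_model`.
#' @export
fluor_model <- function(neg_mean = 1000, neg_sd = 400,
                        pos_mean = 8000, pos_sd = 800,
                        quality_low_fraction = 0.02) {
  check_number(neg_sd, "neg_sd", min = 0)
  check_number(pos_sd, "pos_sd", min = 0)
  check_number(quality_low_fraction, "quality_low_fraction", min = 0, max = 1)
  if (pos_mean <= neg_mean) {
    stop_input("`pos_mean` must exceed `neg_mean`.", "mosaicdpcr_config_error")
  }
  out <- tibble::tibble(neg_mean = neg_mean, neg_sd = neg_sd,
                        pos_mean = pos_mean, pos_sd = pos_sd,
                        quality_low_fraction = quality_low_fraction)
  class(out) <- c("fluor_model", class(out))
  out
}

#' Ground-truth parameters for a simulated chip
#'
#' @param dna_conc Input DNA concentration, ng/ul.
#' @param dna_volume Volume of DNA added to the reaction, ul.
#' @param het_cell_fraction Fraction of genomes coming from heterozygous
#'   mutant cells, in `[0, 1]`. This is the relative mutation abundance (RMA)
#'   expressed as a fraction: 100% RMA corresponds to pure heterozygous DNA,
#'   i.e. a mutant allele fraction of 0.5.
#' @param fluor A [fluor_model()].
#' @param dropout_rate Fraction of wells that fail loading; such wells carry
#'   no template signal and score below the quality threshold.
#' @param seed Integer seed; the same seed and parameters reproduce the chip
#'   bit for bit.
#' @return A list of class `sim_params`.
#' @examples
#' sim_params(het_cell_fraction = 0.03, seed = 1)
#' @export
sim_params <- function(dna_conc = 5, dna_volume = 1, het_cell_fraction = 0,
                       fluor = fluor_model(), dropout_rate = 0.05,
                       seed = NULL) {
  check_number(dna_conc, "dna_conc", min = 0)
  check_number(dna_volume, "dna_volume", min = 0)
  check_number(het_cell_fraction, "het_cell_fraction", min = 0, max = 1)
  check_number(dropout_rate, "dropout_rate", min = 0, max = 1 - 1e-12)
  stopifnot(inherits(fluor, "fluor_model"))
  structure(
    list(dna_conc = dna_conc, dna_volume = dna_volume,
         het_cell_fraction = het_cell_fraction, fluor = fluor,
         dropout_rate = dropout_rate, seed = seed),
    class = "sim_params"
  )
}
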