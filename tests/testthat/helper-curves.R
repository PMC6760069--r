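# Shared fixtures built in code.

curve_604 <- function() {
  calibrator_from_summary(
    dplyr::filter(gnas_calibrators(), target_variant == "c.604C>T"),
    gnas_assay("c.604C>T")
  )
}

curve_605 <- function() {
  calibrator_from_summary(
    dplyr::filter(gnas_calibrators(), target_variant == "c.605G>A"),
    gnas_assay("c.605G>A")
  )
}

# dna_conc that produces a given per-well Poisson mean at het_cell_fraction 1
conc_for_lambda <- function(lambda, spec = chip_spec()) {
  lambda * spec$n_partitions * 2 * 0.0033
}

# a tiny synthetic cohort sheet written to a temp file
write_cohort_sheet <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path)
  path
}

empty_cohort_row <- function(patient_id, tissue, ...) {
  base <- tibble::tibble(
    patient_id = patient_id, tissue = tissue,
    sanger_604 = "WT", aspcr_604 = "WT", dpcr_call_604 = "WT",
    dpcr_cpm_604 = 0, dpcr_rma_604 = "", cold_call_604 = "", cold_rma_604 = "",
    sanger_605 = "WT", aspcr_605 = "WT", dpcr_call_605 = "WT",
    dpcr_cpm_605 = 0, dpcr_rma_605 = "", cold_call_605 = "", cold_rma_605 = ""
  )
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}
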