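#' Classify partitions and apply chip-level QC
#'
#' Wells scoring strictly above the quality threshold are valid; valid wells
#' whose FAM signal lies strictly above the assay's RFU threshold are
#' positive. Both inequalities are strict, matching the validated analysis
#' settings ("quality over 0.6", "RFU > 3000/5000"): a well sitting exactly on
#' a threshold is excluded. A chip passes QC when at least
#' `min_valid_partitions` wells are valid; a failing chip still returns its
#' counts, and downstream quantification flags the result as non-reportable
#' rather than erroring, mirroring analyst review.
#'
#' @param chip A `chip_data` tibble, or any data frame with `fam_rfu` and
#'   `quality` columns (supply `rfu_threshold` in that case).
#' @param policy A [qc_policy()].
#' @param rfu_threshold Positive-call threshold in RFU; defaults to the
#'   threshold of the assay attached to `chip`.
#' @return A one-row tibble of class `partition_summary` with `n_total`,
#'   `n_valid`, `n_positive` and `qc_pass`; the chip geometry is carried along
#'   as an attribute for [poisson_cpm()].
#' @examples
#' chip <- simulate_chip(sim_params(het_cell_fraction = 0.25, seed = 1))
#' call_partitions(chip)
#' @export
call_partitions <- function(chip, policy = qc_policy(), rfu_threshold = NULL) {
  if (nrow(chip) == 0L) {
    stop_input("Chip has no wells.", "mosaicdpcr_input_error")
  }
  if (!all(c("fam_rfu", "quality") %in% names(chip))) {
    stop_input("Chip data needs `fam_rfu` and `quality` columns.",
               "mosaicdpcr_input_error")
  }
  if (is.null(rfu_threshold)) {
    assay <- chip_assay(chip)
    if (is.null(assay)) {
      stop_input("No assay attached to the chip; supply `rfu_threshold`.",
                 "mosaicdpcr_input_error")
    }
    rfu_threshold <- assay$rfu_threshold
  }
  check_number(rfu_threshold, "rfu_threshold", min = 0, strict_min = TRUE)

  valid <- chip$quality > policy$min_quality
  positive <- valid & chip$fam_rfu > rfu_threshold
  out <- tibble::tibble(
    n_total = nrow(chip),
    n_valid = sum(valid),
    n_positive = sum(positive),
    qc_pass = sum(valid) >= policy$min_valid_partitions
  )
  structure(out,
            spec = chip_geometry(chip),
            policy = policy,
            class = c("partition_summary", class(tibble::tibble())))
}
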