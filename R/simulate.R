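#' Convert DNA mass to haploid genome copies
#'
#' One haploid human genome weighs 0.0033 ng, so `mass_ng / 0.0033` genome
#' copies are present in `mass_ng` of DNA. The map is exactly linear; no
#' rounding is applied.
#'
#' @param mass_ng DNA mass in ng (vectorised, each element >= 0).
#' @param genome_mass_ng Mass of one haploid genome, ng.
#' @return Haploid genome copies (real-valued).
#' @examples
#' mass_to_copies(0.0033)  # one genome
#' mass_to_copies(5)       # 1515.15...
#' @export
mass_to_copies <- function(mass_ng, genome_mass_ng = 0.0033) {
  if (!is.numeric(mass_ng) || anyNA(mass_ng)) {
    stop_input("`mass_ng` must be numeric and non-missing.", "mosaicdpcr_domain_error")
  }
  if (any(mass_ng < 0)) {
    stop_input("`mass_ng` must be non-negative.", "mosaicdpcr_domain_error")
  }
  check_number(genome_mass_ng, "genome_mass_ng", min = 0, strict_min = TRUE)
  mass_ng / genome_mass_ng
}

#' Simulate one digital-PCR chip
#'
#' Emulates a mutant-detection chip run with known ground truth. The total
#' haploid copy number is `mass_to_copies(dna_conc * dna_volume)`; a fraction
#' `het_cell_fraction` of genomes come from heterozygous mutant cells, each
#' carrying the mutant allele on one of its two alleles, so the expected
#' mutant copy number is `copies * het_cell_fraction / 2`. Mutant copies fall
#' into wells as independent Poisson counts with per-well mean
#' `mutant_copies * partition_volume / loaded_volume`. Wells holding at least
#' one mutant copy (and not lost to loading dropout) draw their FAM signal
#' from the positive fluorescence component, all other wells from the
#' negative component. Only the mutant channel is modelled: wild-type
#' template does not light up the FAM reporter of these assays.
#'
#' Given the same seed and parameters the output is reproducible bit for bit.
#' The caller's RNG state is left untouched when a seed is supplied.
#'
#' @param params A [sim_params()] object.
#' @param assay A one-row assay definition, see [gnas_assay()].
#' @param spec A [chip_spec()].
#' @return A tibble of class `chip_data` with one row per well (`well_index`,
#'   `fam_rfu`, `quality`) and the assay, chip geometry and simulation truth
#'   attached as attributes (see [chip_truth()]).
#' @examples
#' chip <- simulate_chip(sim_params(het_cell_fraction = 0.25, seed = 7))
#' chip
#' chip_truth(chip)$mutant_copies
#' @export
simulate_chip <- function(params, assay = gnas_assay("c.605G>A"),
                          spec = chip_spec()) {
  stopifnot(inherits(params, "sim_params"))
  n <- spec$n_partitions

  draw <- function() {
    copies <- mass_to_copies(params$dna_conc * params$dna_volume)
    mutant_copies <- copies * params$het_cell_fraction * 0.5
    lambda <- mutant_copies * spec$partition_volume / spec$loaded_volume
    counts <- stats::rpois(n, lambda)
    dropped <- stats::runif(n) < params$dropout_rate
    lit <- counts >= 1L & !dropped
    fm <- params$fluor
    rfu <- ifelse(lit,
                  stats::rnorm(n, fm$pos_mean, fm$pos_sd),
                  stats::rnorm(n, fm$neg_mean, fm$neg_sd))
    low_q <- dropped | stats::runif(n) < fm$quality_low_fraction
    quality <- ifelse(low_q,
                      stats::runif(n, 0, 0.6),
                      stats::runif(n, 0.6, 1))
    wells <- tibble::tibble(
      well_index = seq_len(n),
      fam_rfu = pmax(rfu, 0),
      quality = quality
    )
    truth <- list(
      params = params,
      total_copies = copies,
      mutant_copies = mutant_copies,
      lambda_per_well = lambda,
      true_cpm = mutant_copies / spec$loaded_volume,
      template_wells = sum(counts >= 1L)
    )
    new_chip_data(wells, assay = assay, spec = spec, truth = truth)
  }

  if (!is.null(params$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(params$seed)
  }
  draw()
}

new_chip_data <- function(wells, assay, spec, truth = NULL) {
  structure(
    wells,
    assay = assay,
    spec = spec,
    truth = truth,
    class = c("chip_data", class(tibble::tibble()))
  )
}

#' Accessors for chip metadata
#'
#' @param chip A `chip_data` tibble from [simulate_chip()] or
#'   [read_chip_csv()].
#' @return `chip_truth()` returns the simulation ground truth (or `NULL` for
#'   instrument data); `chip_assay()` and `chip_geometry()` the attached assay
#'   definition and [chip_spec()].
#' @export
chip_truth <- function(chip) attr(chip, "truth", exact = TRUE)

#' @rdname chip_truth
#' @export
chip_assay <- function(chip) attr(chip, "assay", exact = TRUE)

#' @rdname chip_truth
#' @export
chip_geometry <- function(chip) attr(chip, "spec", exact = TRUE)

#' Write / read a chip as CSV plus JSON sidecar
#'
#' The CSV holds one row per well (`well_index,fam_rfu,quality`, header
#' mandatory); assay identity, chip geometry and any simulation truth go to a
#' JSON sidecar with the same basename.
#'
#' @param chip A `chip_data` tibble.
#' @param path CSV path; the sidecar replaces the extension with `.json`.
#' @return `write_chip_csv()` returns `path` invisibly; `read_chip_csv()`
#'   returns the reconstructed `chip_data` tibble.
#' @export
write_chip_csv <- function(chip, path) {
  readr::write_csv(tibble::as_tibble(chip), path)
  truth <- chip_truth(chip)
  meta <- list(
    assay = as.list(chip_assay(chip)),
    spec = as.list(tibble::as_tibble(chip_geometry(chip)))
  )
  if (!is.null(truth)) {
    p <- truth$params
    meta$truth <- list(
      dna_conc = p$dna_conc, dna_volume = p$dna_volume,
      het_cell_fraction = p$het_cell_fraction,
      dropout_rate = p$dropout_rate, seed = p$seed,
      mutant_copies = truth$mutant_copies,
      lambda_per_well = truth$lambda_per_well,
      true_cpm = truth$true_cpm
    )
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chip_csv
#' @export
read_chip_csv <- function(path) {
  wells <- readr::read_csv(path, col_types = readr::cols(
    well_index = readr::col_integer(),
    fam_rfu = readr::col_double(),
    quality = readr::col_double()
  ))
  meta_path <- sidecar_path(path)
  assay <- gnas_assays()[1, ]
  spec <- chip_spec(n_partitions = nrow(wells),
                    partition_volume = 15 / nrow(wells))
  truth <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    assay <- tibble::as_tibble(meta$assay)
    spec <- chip_spec(meta$spec$n_partitions, meta$spec$partition_volume,
                      meta$spec$loaded_volume)
    truth <- meta$truth
  }
  new_chip_data(wells, assay = assay, spec = spec, truth = truth)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)
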