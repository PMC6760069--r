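#' Assemble a pipeline configuration
#'
#' Gathers every tunable of the analysis with defaults equal to the validated
#' constants: RFU thresholds 5000 (c.604C>T) and 3000 (c.605G>A), per-well
#' quality over 0.6 with a 10,000-point floor, 20,000 wells holding 15 ul,
#' genome mass 0.0033 ng and dilution factor 3.34.
#'
#' @param assays Assay definition table, see [gnas_assays()].
#' @param qc A [qc_policy()].
#' @param constants A [quant_constants()].
#' @param chip A [chip_spec()].
#' @param calibrator_file Optional TSV of calibrator replicates (columns
#'   `assay_id`, `rma_percent`, `replicate`, `cpm`); when `NULL` the packaged
#'   printed summaries ([gnas_calibrators()]) are used.
#' @param cohort_file Cohort sheet TSV; defaults to the packaged
#'   transcription.
#' @param alpha Significance level for cutoff selection.
#' @param seed Integer seed for any simulation stage.
#' @param outdir Output directory for reports (`NULL` for no files).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(assays = gnas_assays(), qc = qc_policy(),
                            constants = quant_constants(), chip = chip_spec(),
                            calibrator_file = NULL,
                            cohort_file = cohort_fixture_path(),
                            alpha = 0.05, seed = 1L, outdir = NULL) {
  structure(
    list(assays = assays, qc = qc, constants = constants, chip = chip,
         calibrator_file = calibrator_file, cohort_file = cohort_file,
         alpha = alpha, seed = seed, outdir = outdir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Builds a calibrator curve and positivity cutoff per assay, derives the
#' limit of detection, loads the cohort sheet, recomputes digital-PCR calls
#' from the recorded cpm values against the cutoffs, and tabulates detection
#' rates (per tissue class, per patient, on the fully tested subcohort) and
#' false-negative counts for all four methods. When `outdir` is set, a JSON
#' report (with the configuration snapshot and MD5 hashes of the inputs) and
#' TSV detection tables are written; identical configuration and seed give
#' byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return A list of class `dpcr_report`: `calibration` (per-assay curve,
#'   cutoff, LOD), `cohort`, `recomputed_calls`, `detection`,
#'   `patient_rates`, `subcohort`, `false_negatives`, `config_snapshot`.
#' @examples
#' rep <- run_pipeline(pipeline_config(), quiet = TRUE)
#' rep$detection$DPCR
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$calibrator_file) && !file.exists(config$calibrator_file)) {
    stop_input(sprintf("Calibrator file '%s' not found.", config$calibrator_file),
               "mosaicdpcr_startup_error")
  }
  if (!file.exists(config$cohort_file)) {
    stop_input(sprintf("Cohort file '%s' not found.", config$cohort_file),
               "mosaicdpcr_startup_error")
  }

  # calibration stage
  calib_src <- if (is.null(config$calibrator_file)) {
    gnas_calibrators()
  } else {
    readr::read_tsv(config$calibrator_file, show_col_types = FALSE)
  }
  calibration <- purrr::map(seq_len(nrow(config$assays)), function(i) {
    assay <- config$assays[i, ]
    rows <- calib_src[calib_src$assay_id == assay$assay_id, ]
    curve <- if ("cpm" %in% names(rows)) {
      build_calibrator(rows, assay)
    } else {
      calibrator_from_summary(rows, assay)
    }
    cutoff <- determine_cutoff(curve, alpha = config$alpha)
    list(assay = assay, curve = curve, cutoff = cutoff,
         lod_ng_per_ul = compute_lod(cutoff, config$constants))
  })
  names(calibration) <- config$assays$assay_id
  say("calibration: %d assays, cutoffs %s cpm",
      length(calibration),
      paste(purrr::map_dbl(calibration, ~ .x$cutoff$cpm_mean), collapse = "/"))

  # cohort stage
  cohort <- load_cohort(config$cohort_file)
  say("cohort: %d samples, %d patients in", nrow(cohort),
      dplyr::n_distinct(cohort$patient_id))

  cut604 <- calibration[[config$assays$assay_id[config$assays$target_variant == "c.604C>T"]]]$cutoff
  cut605 <- calibration[[config$assays$assay_id[config$assays$target_variant == "c.605G>A"]]]$cutoff
  recomputed <- cohort |>
    dplyr::transmute(
      .data$patient_id, .data$tissue_label,
      recomputed_604 = call_sample(.data$dpcr_cpm_604, cut604),
      recorded_604 = .data$dpcr_call_604,
      recomputed_605 = call_sample(.data$dpcr_cpm_605, cut605),
      recorded_605 = .data$dpcr_call_605
    ) |>
    dplyr::mutate(concordant = .data$recomputed_604 == .data$recorded_604 &
                    .data$recomputed_605 == .data$recorded_605)
  say("classification: %d/%d samples concordant with recorded calls",
      sum(recomputed$concordant), nrow(recomputed))

  detection <- purrr::map(rlang::set_names(COHORT_METHODS),
                          ~ detection_table(cohort, .x))
  patient_rates <- purrr::map_dfr(COHORT_METHODS, ~ patient_rate(cohort, .x))
  subcohort <- subcohort_comparison(cohort)
  fn <- purrr::map_int(rlang::set_names(setdiff(COHORT_METHODS, "DPCR")),
                       ~ false_negative_count(cohort, .x))
  say("tabulation: %d methods out", length(detection))

  snapshot <- list(
    assays = as.list(config$assays),
    qc = as.list(tibble::as_tibble(config$qc)),
    constants = as.list(tibble::as_tibble(config$constants)),
    chip = as.list(tibble::as_tibble(config$chip)),
    alpha = config$alpha, seed = config$seed,
    inputs = list(
      cohort_file = basename(config$cohort_file),
      cohort_md5 = unname(tools::md5sum(config$cohort_file)),
      calibrator_file = if (is.null(config$calibrator_file)) "builtin summaries"
                        else basename(config$calibrator_file),
      calibrator_md5 = if (is.null(config$calibrator_file)) NULL
                       else unname(tools::md5sum(config$calibrator_file))
    )
  )

  report <- structure(
    list(calibration = calibration, cohort = cohort,
         recomputed_calls = recomputed, detection = detection,
         patient_rates = patient_rates, subcohort = subcohort,
         false_negatives = fn, config_snapshot = snapshot),
    class = "dpcr_report"
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    json <- list(
      config = snapshot,
      calibration = purrr::map(calibration, function(x) {
        list(assay_id = x$assay$assay_id,
             cutoff = as.list(tibble::as_tibble(x$cutoff)),
             lod_ng_per_ul = x$lod_ng_per_ul,
             points = as.list(tibble::as_tibble(x$curve)))
      }),
      detection = purrr::map(detection, ~ as.list(tibble::as_tibble(.x))),
      patient_rates = as.list(patient_rates),
      subcohort = as.list(tibble::as_tibble(subcohort)),
      false_negatives = as.list(fn)
    )
    jsonlite::write_json(json, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (m in names(detection)) {
      readr::write_tsv(tibble::as_tibble(detection[[m]]),
                       file.path(config$outdir,
                                 sprintf("detection_%s.tsv", tolower(m))))
    }
    say("reports written to %s", config$outdir)
  }
  report
}

#' @export
print.dpcr_report <- function(x, ...) {
  cat("Digital PCR mosaicism report\n")
  for (a in names(x$calibration)) {
    cal <- x$calibration[[a]]
    cat(sprintf("  %s (%s): cutoff %.3f cpm at %g%% RMA (p = %.4f), LOD %.2f ng/ul\n",
                a, cal$assay$target_variant, cal$cutoff$cpm_mean,
                cal$cutoff$rma_percent, cal$cutoff$p_value, cal$lod_ng_per_ul))
  }
  cat(sprintf("  cohort: %d samples / %d patients\n",
              nrow(x$cohort), dplyr::n_distinct(x$cohort$patient_id)))
  pr <- x$patient_rates
  cat(sprintf("  patient detection: %s\n",
              paste(sprintf("%s %d/%d (%.1f%%)", pr$method, pr$positives,
                            pr$tested, pr$rate), collapse = ", ")))
  invisible(x)
}

#' Write the packaged data fixtures to a directory
#'
#' Materialises the inputs of the pipeline as files: the cohort sheet
#' transcription (`cohort_table1.tsv`, data, hence seed-independent),
#' calibrator replicate TSVs whose triplicates reproduce each printed
#' mean/SD exactly (the moment-matched pattern mean + sd * (-1, 0, 1)), and a
#' set of simulated chip CSVs spanning the RMA grid 0-100% (seeded as
#' `seed + replicate index`).
#'
#' @param outdir Writable output directory.
#' @param seed Base seed for the simulated chips.
#' @param rma_grid RMA percentages to simulate chips at.
#' @return Invisibly, the character vector of files written.
#' @export
make_fixtures <- function(outdir, seed = 1L,
                          rma_grid = c(0, 1.5, 3, 6, 12.5, 25, 50, 100)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  cohort_path <- file.path(outdir, "cohort_table1.tsv")
  file.copy(cohort_fixture_path(), cohort_path, overwrite = TRUE)
  files <- c(files, cohort_path)

  reps <- gnas_calibrators() |>
    dplyr::rowwise() |>
    dplyr::reframe(
      assay_id = .data$assay_id,
      rma_percent = .data$rma_percent,
      replicate = 1:3,
      cpm = pmax(.data$mean_cpm + .data$sd_cpm * c(-1, 0, 1), 0)
    )
  for (id in unique(reps$assay_id)) {
    p <- file.path(outdir, sprintf("calibrator_%s.tsv", id))
    readr::write_tsv(reps[reps$assay_id == id, ], p)
    files <- c(files, p)
  }

  for (i in seq_along(rma_grid)) {
    chip <- simulate_chip(
      sim_params(het_cell_fraction = rma_grid[i] / 100, seed = seed + i),
      assay = gnas_assay("c.605G>A")
    )
    p <- file.path(outdir, sprintf("chip_rma%s.csv",
                                   gsub("\\.", "_", format(rma_grid[i]))))
    write_chip_csv(chip, p)
    files <- c(files, p, sidecar_path(p))
  }
  invisible(files)
}
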