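# Cohort sheet handling and detection-rate tabulation.
#
# A cohort sheet has one row per tissue sample and, per variant (c.604C>T,
# c.605G>A), the call of each method plus the digital-PCR cpm and RMA label.
# "nd" or blank cells mean the sample was not tested by that method.

TISSUE_CODES <- c("BL", "BO", "CB", "FB", "OT", "OC", "OCL")
TISSUE_CLASSES <- c("BO", "CB/FB", "OC/OCL/OT", "BL")
COHORT_METHODS <- c("SANGER", "ASPCR", "COLD", "DPCR")

#' Map tissue codes to the four reporting classes
#'
#' Bone (BO), cutaneous biopsy / fibroblasts (CB/FB), ovarian material
#' (OC/OCL/OT) and blood (BL) partition all tissue codes.
#'
#' @param code Character vector of tissue codes (suffixes like `"BO-LJ"` are
#'   reduced to their leading code).
#' @return Factor with levels `BO`, `CB/FB`, `OC/OCL/OT`, `BL`.
#' @examples
#' tissue_class(c("BO-LJ", "FB", "OCL", "BL"))
#' @export
tissue_class <- function(code) {
  base <- sub("-.*$", "", code)
  bad <- setdiff(unique(base), TISSUE_CODES)
  if (length(bad) > 0) {
    stop_input(sprintf("Unknown tissue code(s): %s.", paste(bad, collapse = ", ")),
               "mosaicdpcr_parse_error")
  }
  cls <- dplyr::case_match(
    base,
    "BO" ~ "BO",
    c("CB", "FB") ~ "CB/FB",
    c("OC", "OCL", "OT") ~ "OC/OCL/OT",
    "BL" ~ "BL"
  )
  factor(cls, levels = TISSUE_CLASSES)
}

norm_call <- function(x, column, rows) {
  x <- toupper(trimws(ifelse(is.na(x), "", x)))
  x[x %in% c("", "ND")] <- "ND"
  bad <- !x %in% c("MUT", "WT", "ND")
  if (any(bad)) {
    stop_input(sprintf("Invalid call '%s' in column %s (row %d).",
                       x[which(bad)[1]], column, rows[which(bad)[1]]),
               "mosaicdpcr_parse_error")
  }
  x
}

#' Load a cohort sample sheet
#'
#' Reads a TSV with columns `patient_id`, `tissue`, then per variant the
#' seven columns `sanger_*`, `aspcr_*`, `dpcr_call_*`, `dpcr_cpm_*`,
#' `dpcr_rma_*`, `cold_call_*`, `cold_rma_*` (suffixes `604` and `605`).
#' Blank or "nd" calls become `"ND"` (not tested); tissue suffixes such as
#' `"BO-LJ"` keep their label but are classed by their leading code. Unknown
#' tissue codes or duplicated (patient, tissue label) rows are parse errors
#' naming the offending row.
#'
#' @param sheet Path to the TSV. Defaults to the packaged cohort
#'   transcription ([cohort_fixture_path()]).
#' @return A tibble of class `gnas_cohort`, one row per sample, with
#'   `patient_id`, `tissue_label`, `tissue_code`, `tissue_class` and the
#'   normalised per-method columns.
#' @examples
#' cohort <- load_cohort()
#' nrow(cohort)  # 79 samples
#' @export
load_cohort <- function(sheet = cohort_fixture_path()) {
  raw <- readr::read_tsv(sheet, col_types = readr::cols(.default = readr::col_character()))
  need <- c("patient_id", "tissue",
            paste0(rep(c("sanger_", "aspcr_", "dpcr_call_", "dpcr_cpm_",
                         "dpcr_rma_", "cold_call_", "cold_rma_"), 2),
                   rep(c("604", "605"), each = 7)))
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop_input(sprintf("Cohort sheet is missing column(s): %s.",
                       paste(missing, collapse = ", ")),
               "mosaicdpcr_parse_error")
  }
  rows <- seq_len(nrow(raw))
  dup <- duplicated(raw[c("patient_id", "tissue")])
  if (any(dup)) {
    stop_input(sprintf("Duplicate (patient, tissue) row %d: patient %s, tissue %s.",
                       which(dup)[1], raw$patient_id[which(dup)[1]],
                       raw$tissue[which(dup)[1]]),
               "mosaicdpcr_parse_error")
  }
  call_cols <- grep("^(sanger|aspcr|dpcr_call|cold_call)_", need, value = TRUE)
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    tissue_label = raw$tissue,
    tissue_code = sub("-.*$", "", raw$tissue),
    tissue_class = tissue_class(raw$tissue)
  )
  for (col in call_cols) out[[col]] <- norm_call(raw[[col]], col, rows)
  for (col in c("dpcr_cpm_604", "dpcr_cpm_605")) {
    out[[col]] <- readr::parse_double(ifelse(raw[[col]] %in% c("", NA), NA, raw[[col]]))
  }
  for (col in c("dpcr_rma_604", "dpcr_rma_605", "cold_rma_604", "cold_rma_605")) {
    out[[col]] <- ifelse(is.na(raw[[col]]) | raw[[col]] == "", NA_character_, raw[[col]])
  }
  structure(out, class = c("gnas_cohort", class(tibble::tibble())))
}

#' Path to the packaged cohort transcription
#'
#' A plain-text transcription of the published per-sample results table
#' (79 samples from 54 patients across blood, bone, cutaneous and ovarian
#' tissues, with Sanger, AS-PCR, COLD-MAMA PCR and digital PCR results per
#' variant).
#'
#' @return Path to `cohort_table1.tsv` inside the installed package.
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "cohort_table1.tsv", package = "mosaicdpcr",
              mustWork = TRUE)
}

method_cols <- function(method) {
  method <- match.arg(toupper(method), COHORT_METHODS)
  prefix <- c(SANGER = "sanger", ASPCR = "aspcr", COLD = "cold_call",
              DPCR = "dpcr_call")[[method]]
  paste0(prefix, c("_604", "_605"))
}

#' Per-sample positivity and tested status for one method
#'
#' A sample is positive for a method when either variant's call is MUT, and
#' tested when at least one variant has a non-ND result. A sample mutant for
#' either variant counts once.
#'
#' @param records A `gnas_cohort` tibble from [load_cohort()].
#' @param method One of `"SANGER"`, `"ASPCR"`, `"COLD"`, `"DPCR"`.
#' @return A tibble with `patient_id`, `tissue_label`, `tissue_class`,
#'   `tested`, `positive`.
#' @export
method_calls <- function(records, method) {
  cols <- method_cols(method)
  a <- records[[cols[1]]]
  b <- records[[cols[2]]]
  tibble::tibble(
    patient_id = records$patient_id,
    tissue_label = records$tissue_label,
    tissue_class = records$tissue_class,
    tested = a != "ND" | b != "ND",
    positive = a == "MUT" | b == "MUT"
  )
}

rate_percent <- function(num, den, round_mode = c("half_up", "truncate")) {
  round_mode <- match.arg(round_mode)
  raw <- 100 * num / den
  out <- switch(round_mode,
                half_up = round_half_up(raw, 1),
                truncate = trunc(round(raw * 10, 9)) / 10)
  ifelse(den == 0, NA_real_, out)
}

#' Detection-rate table for one method
#'
#' Tabulates, per tissue class, the samples called mutant (either variant)
#' over the samples with at least one non-ND result for that method, plus an
#' all-samples row and a patient-level row (patients with any mutant sample
#' over patients with any tested sample). Rates are percentages to one
#' decimal; `round_mode = "truncate"` reproduces the repeating-decimal cells
#' (10/15 printed as 66.6%, 2/11 as 18.1%) of the published table.
#'
#' @inheritParams method_calls
#' @param round_mode `"half_up"` (default) or `"truncate"`.
#' @return A tibble of class `detection_table` with columns `group`,
#'   `positives`, `tested`, `rate`; the `method` is kept as an attribute.
#' @examples
#' detection_table(load_cohort(), "DPCR")
#' @export
detection_table <- function(records, method, round_mode = c("half_up", "truncate")) {
  round_mode <- match.arg(round_mode)
  calls <- method_calls(records, method)
  by_class <- calls |>
    dplyr::group_by(tissue_class = factor(.data$tissue_class, levels = TISSUE_CLASSES)) |>
    dplyr::summarise(positives = sum(.data$positive & .data$tested),
                     tested = sum(.data$tested), .groups = "drop") |>
    tidyr::complete(.data$tissue_class,
                    fill = list(positives = 0L, tested = 0L)) |>
    dplyr::transmute(group = as.character(.data$tissue_class),
                     positives = as.integer(.data$positives),
                     tested = as.integer(.data$tested))
  totals <- tibble::tibble(
    group = "All samples",
    positives = sum(by_class$positives),
    tested = sum(by_class$tested)
  )
  pr <- patient_rate(records, method, round_mode = round_mode)
  patients <- tibble::tibble(group = "Patients",
                             positives = pr$positives, tested = pr$tested)
  out <- dplyr::bind_rows(by_class, totals, patients) |>
    dplyr::mutate(rate = rate_percent(.data$positives, .data$tested, round_mode))
  structure(out, method = toupper(method),
            class = c("detection_table", class(tibble::tibble())))
}

#' Patient-level detection rate for one method
#'
#' A patient is positive when any of their samples is mutant by the method,
#' and tested when any sample has a non-ND result.
#'
#' @inheritParams detection_table
#' @return A one-row tibble: `method`, `positives`, `tested`, `rate`.
#' @examples
#' patient_rate(load_cohort(), "DPCR")  # 23/54, 42.6%
#' @export
patient_rate <- function(records, method, round_mode = c("half_up", "truncate")) {
  round_mode <- match.arg(round_mode)
  per_patient <- method_calls(records, method) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(tested = any(.data$tested),
                     positive = any(.data$positive & .data$tested),
                     .groups = "drop")
  tibble::tibble(
    method = toupper(method),
    positives = sum(per_patient$positive),
    tested = sum(per_patient$tested),
    rate = rate_percent(sum(per_patient$positive), sum(per_patient$tested),
                        round_mode)
  )
}

#' Head-to-head comparison on the fully tested subcohort
#'
#' Restricts the cohort to patients with at least one non-ND result for every
#' one of the four methods, then computes the patient-level detection rate of
#' each method within that subcohort (the common denominator makes the
#' methods directly comparable).
#'
#' @inheritParams detection_table
#' @return A tibble with one row per method (`method`, `positives`, `tested`,
#'   `rate`); the subcohort patient ids are kept as attribute `patients`.
#' @examples
#' subcohort_comparison(load_cohort())
#' @export
subcohort_comparison <- function(records, round_mode = c("half_up", "truncate")) {
  round_mode <- match.arg(round_mode)
  tested_by <- purrr::map(COHORT_METHODS, function(m) {
    calls <- method_calls(records, m)
    unique(calls$patient_id[calls$tested])
  })
  subcohort <- purrr::reduce(tested_by, intersect)
  if (length(subcohort) == 0L) {
    out <- tibble::tibble(method = COHORT_METHODS, positives = 0L,
                          tested = 0L, rate = NA_real_)
    return(structure(out, patients = character(0), class = class(out)))
  }
  sub <- records[records$patient_id %in% subcohort, ]
  out <- purrr::map_dfr(COHORT_METHODS, function(m) {
    pr <- patient_rate(sub, m, round_mode = round_mode)
    pr$tested <- length(subcohort)
    pr$rate <- rate_percent(pr$positives, pr$tested, round_mode)
    pr
  })
  structure(out, patients = subcohort, class = class(out))
}

#' Patients missed by one method but found by a reference method
#'
#' Counts patients positive by the reference method (digital PCR by default)
#' who were tested by `other` yet negative by it: the reference method's view
#' of the other method's false negatives.
#'
#' @inheritParams detection_table
#' @param other Method whose false negatives are counted.
#' @param reference Reference method (default `"DPCR"`).
#' @return Integer count of patients.
#' @examples
#' false_negative_count(load_cohort(), "SANGER")  # 19
#' @export
false_negative_count <- function(records, other, reference = "DPCR") {
  ref <- method_calls(records, reference) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(positive = any(.data$positive & .data$tested), .groups = "drop")
  oth <- method_calls(records, other) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(tested = any(.data$tested),
                     positive = any(.data$positive & .data$tested), .groups = "drop")
  joined <- dplyr::inner_join(ref, oth, by = "patient_id",
                              suffix = c("_ref", "_other"))
  sum(joined$positive_ref & joined$tested & !joined$positive_other)
}
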