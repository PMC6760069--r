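cohort <- load_cohort()

test_that("the packaged cohort sheet loads into 79 normalised sample records", {
  expect_s3_class(cohort, "gnas_cohort")
  expect_equal(nrow(cohort), 79L)
  expect_equal(dplyr::n_distinct(cohort$patient_id), 54L)
  expect_equal(sum(cohort$tissue_class == "BL"), 37L)
  expect_equal(sum(cohort$tissue_class == "BO"), 15L)
  expect_equal(sum(cohort$tissue_class == "CB/FB"), 16L)
  expect_equal(sum(cohort$tissue_class == "OC/OCL/OT"), 11L)
  # suffixed tissue labels keep their label but class by leading code
  lj <- cohort[cohort$tissue_label == "BO-LJ", ]
  expect_equal(as.character(lj$tissue_class), "BO")
  # "nd" and blank both mean not tested
  expect_equal(cohort$cold_call_604[cohort$patient_id == "5"], "ND")
  blank_cold <- cohort[cohort$patient_id == "43" & cohort$tissue_label == "BL", ]
  expect_equal(blank_cold$cold_call_604, "ND")
  expect_equal(blank_cold$cold_call_605, "ND")
  expect_false(anyNA(cohort$dpcr_cpm_604))
})

test_that("malformed sheets fail loudly with the offending row named", {
  dup <- dplyr::bind_rows(empty_cohort_row("1", "BO"), empty_cohort_row("1", "BO"))
  expect_error(load_cohort(write_cohort_sheet(dup)),
               "patient 1", class = "mosaicdpcr_parse_error")
  bad_tissue <- empty_cohort_row("1", "XX")
  expect_error(load_cohort(write_cohort_sheet(bad_tissue)),
               "XX", class = "mosaicdpcr_parse_error")
  bad_call <- empty_cohort_row("1", "BO", sanger_604 = "MAYBE")
  expect_error(load_cohort(write_cohort_sheet(bad_call)),
               class = "mosaicdpcr_parse_error")
  missing_col <- empty_cohort_row("1", "BO")[, -3]
  expect_error(load_cohort(write_cohort_sheet(missing_col)),
               "sanger_604", class = "mosaicdpcr_parse_error")
})

test_that("digital PCR detection table matches the reference tissue cells", {
  tab <- detection_table(cohort, "DPCR")
  get <- function(g) tab[tab$group == g, ]
  expect_equal(get("BO")$positives, 10L);         expect_equal(get("BO")$tested, 15L)
  expect_equal(get("CB/FB")$positives, 3L);       expect_equal(get("CB/FB")$tested, 16L)
  expect_equal(get("OC/OCL/OT")$positives, 10L);  expect_equal(get("OC/OCL/OT")$tested, 11L)
  expect_equal(get("BL")$positives, 14L);         expect_equal(get("BL")$tested, 37L)
  expect_equal(get("BL")$rate, 37.8)
  expect_equal(get("OC/OCL/OT")$rate, 90.9)
  expect_equal(get("Patients")$positives, 23L)
  expect_equal(get("Patients")$tested, 54L)
  expect_equal(get("Patients")$rate, 42.6)
})

test_that("the lower-sensitivity methods tabulate their reference cells", {
  sanger <- detection_table(cohort, "SANGER")
  expect_equal(sanger$positives[sanger$group == "BL"], 0L)
  expect_equal(sanger$tested[sanger$group == "BL"], 37L)
  expect_equal(sanger$positives[sanger$group == "BO"], 5L)
  expect_equal(sanger$positives[sanger$group == "Patients"], 4L)
  expect_equal(sanger$rate[sanger$group == "Patients"], 7.4)
  aspcr <- detection_table(cohort, "ASPCR")
  expect_equal(aspcr$positives[aspcr$group == "BL"], 3L)
  expect_equal(aspcr$tested[aspcr$group == "BL"], 33L)
  expect_equal(aspcr$rate[aspcr$group == "BL"], 9.1)
  expect_equal(aspcr$tested[aspcr$group == "BO"], 10L)   # nd rows drop out
  expect_equal(aspcr$positives[aspcr$group == "Patients"], 9L)
  expect_equal(aspcr$tested[aspcr$group == "Patients"], 46L)
  expect_equal(aspcr$rate[aspcr$group == "Patients"], 19.6)
  cold <- detection_table(cohort, "COLD")
  expect_equal(cold$tested[cold$group == "BO"], 3L)
  expect_equal(cold$tested[cold$group == "BL"], 11L)
  expect_equal(cold$positives[cold$group == "Patients"], 9L)
  expect_equal(cold$tested[cold$group == "Patients"], 14L)
  expect_equal(cold$rate[cold$group == "Patients"], 64.3)
})

test_that("truncation mode reproduces the repeating-decimal display cells", {
  tab <- detection_table(cohort, "DPCR", round_mode = "truncate")
  expect_equal(tab$rate[tab$group == "BO"], 66.6)       # 10/15
  expect_equal(detection_table(cohort, "SANGER", round_mode = "truncate")$rate[3],
               9.0)                                     # 1/11 OC/OCL/OT
  # half-up stays the default
  expect_equal(detection_table(cohort, "DPCR")$rate[1], 66.7)
})

test_that("tissue-class numerators partition the total positive-sample count", {
  for (m in c("SANGER", "ASPCR", "COLD", "DPCR")) {
    tab <- detection_table(cohort, m)
    classes <- tab[!tab$group %in% c("All samples", "Patients"), ]
    total <- tab[tab$group == "All samples", ]
    expect_equal(sum(classes$positives), total$positives)
    expect_equal(sum(classes$tested), total$tested)
  }
})

test_that("patient-level sensitivity orders the methods on this cohort", {
  # compared on the fully tested subcohort, where denominators are shared
  sub <- subcohort_comparison(cohort)
  rates <- sub$rate[match(c("SANGER", "ASPCR", "COLD", "DPCR"), sub$method)]
  expect_true(all(diff(rates) >= 0))
})

test_that("the fully tested subcohort comparison uses a common denominator", {
  sub <- subcohort_comparison(cohort)
  expect_equal(length(attr(sub, "patients")), 14L)
  expect_equal(sub$tested, rep(14L, 4))
  expect_equal(sub$positives[sub$method == "DPCR"], 10L)
  expect_equal(sub$rate[sub$method == "DPCR"], 71.4)
  expect_equal(sub$positives[sub$method == "SANGER"], 2L)
  expect_equal(sub$rate[sub$method == "SANGER"], 14.3)
  expect_equal(sub$positives[sub$method == "ASPCR"], 5L)
  expect_equal(sub$rate[sub$method == "ASPCR"], 35.7)
  expect_equal(sub$positives[sub$method == "COLD"], 9L)
  expect_equal(sub$rate[sub$method == "COLD"], 64.3)
})

test_that("false negatives count patients missed relative to digital PCR", {
  expect_equal(false_negative_count(cohort, "SANGER"), 19L)
  expect_equal(false_negative_count(cohort, "ASPCR"), 10L)
  expect_equal(false_negative_count(cohort, "COLD"), 1L)
  expect_equal(false_negative_count(cohort, "DPCR"), 0L)  # self-comparison
})

test_that("degenerate cohorts are handled explicitly", {
  empty <- cohort[0, ]
  tab <- detection_table(empty, "DPCR")
  expect_equal(tab$tested, rep(0L, 6))
  expect_true(all(is.na(tab$rate)))
  one <- load_cohort(write_cohort_sheet(empty_cohort_row("1", "BL")))
  pr <- patient_rate(one, "DPCR")
  expect_equal(pr$positives, 0L)
  expect_equal(pr$tested, 1L)
  # no COLD results anywhere -> empty subcohort
  no_cold <- subcohort_comparison(one)
  expect_equal(nrow(no_cold), 4L)
  expect_equal(no_cold$tested, rep(0L, 4))
})
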