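test_that("calibrator points summarise replicates with mean and sample SD", {
  reps <- tibble::tibble(
    rma_percent = rep(c(0, 3, 6), each = 3),
    cpm = c(0.09, 0.10, 0.11, 0.38, 0.39, 0.40, 0.55, 0.55, 0.55)
  )
  curve <- build_calibrator(reps, gnas_assay("c.604C>T"))
  expect_s3_class(curve, "calibrator_curve")
  expect_equal(curve$mean_cpm[curve$rma_percent == 3], 0.39)
  expect_equal(curve$sd_cpm[curve$rma_percent == 3], 0.01)
  expect_equal(curve$sd_cpm[curve$rma_percent == 6], 0)  # degenerate spread
  expect_equal(curve$rma_percent, c(0, 3, 6))            # sorted ascending
})

test_that("curves without a 0% anchor or with single replicates are rejected", {
  expect_error(build_calibrator(tibble::tibble(rma_percent = rep(3, 3),
                                               cpm = c(0.3, 0.4, 0.5)),
                                gnas_assay("c.604C>T")),
               class = "mosaicdpcr_config_error")
  expect_error(build_calibrator(tibble::tibble(rma_percent = c(0, 0, 3),
                                               cpm = c(0.1, 0.1, 0.4)),
                                gnas_assay("c.604C>T")),
               class = "mosaicdpcr_config_error")
  expect_warning(
    calibrator_from_summary(
      tibble::tibble(rma_percent = c(0, 3, 6), mean_cpm = c(0.1, 0.9, 0.5),
                     sd_cpm = 0.01, n_reps = 3L),
      gnas_assay("c.604C>T")),
    class = "mosaicdpcr_monotonicity_warning")
})

test_that("triplicates simulated at the reference dilution means recover the curve", {
  ref <- dplyr::filter(gnas_calibrators(), target_variant == "c.605G>A")
  withr::with_seed(42, {
    reps <- tidyr::uncount(ref, 3) |>
      dplyr::mutate(cpm = pmax(stats::rnorm(dplyr::n(), mean_cpm, sd_cpm), 0))
  })
  curve <- suppressWarnings(build_calibrator(reps, gnas_assay("c.605G>A")))
  for (i in seq_len(nrow(ref))) {
    se <- ref$sd_cpm[i] / sqrt(3)
    expect_lt(abs(curve$mean_cpm[curve$rma_percent == ref$rma_percent[i]] -
                    ref$mean_cpm[i]),
              max(3 * se, 1e-9))
  }
})

test_that("summary-statistics t-test matches stats::t.test on raw replicates", {
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(3, 1, 0.3)
      y <- rnorm(4, 0.2, 0.1)
      for (ve in c(TRUE, FALSE)) {
        mine <- summary_t_test(mean(x), sd(x), 3, mean(y), sd(y), 4, var_equal = ve)
        ref <- stats::t.test(x, y, var.equal = ve)
        expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
      }
    }
  })
})

test_that("degenerate zero-variance groups give a decisive p-value", {
  expect_equal(summary_t_test(1, 0, 3, 1, 0, 3)$p_value, 1)
  expect_equal(summary_t_test(1, 0, 3, 0, 0, 3)$p_value, 0)
})

test_that("cutoff selection picks the reported dilution points", {
  k604 <- determine_cutoff(curve_604())
  expect_equal(k604$cpm_mean, 0.391)
  expect_equal(k604$rma_percent, 3)
  expect_equal(k604$p_value, 0.002742032, tolerance = 1e-6)
  k605 <- determine_cutoff(curve_605())
  expect_equal(k605$cpm_mean, 0.464)
  expect_equal(k605$rma_percent, 1.5)
  expect_equal(k605$p_value, 0.0003606635, tolerance = 1e-6)
  # Welch flavour moves the p-values but not the selected points
  expect_equal(determine_cutoff(curve_604(), var_equal = FALSE)$cpm_mean, 0.391)
  expect_equal(determine_cutoff(curve_605(), var_equal = FALSE)$cpm_mean, 0.464)
})

test_that("selection skips points indistinguishable from background", {
  sums <- tibble::tibble(
    rma_percent = c(0, 1, 3),
    mean_cpm = c(0.100, 0.101, 0.500),
    sd_cpm = c(0.02, 0.02, 0.02),
    n_reps = 3L
  )
  k <- determine_cutoff(calibrator_from_summary(sums, gnas_assay("c.604C>T")))
  expect_equal(k$rma_percent, 3)
  expect_equal(k$cpm_mean, 0.5)
  flat <- tibble::tibble(rma_percent = c(0, 3), mean_cpm = c(0.1, 0.11),
                         sd_cpm = 0.05, n_reps = 3L)
  expect_error(determine_cutoff(calibrator_from_summary(flat, gnas_assay("c.604C>T"))),
               class = "mosaicdpcr_no_cutoff_error")
})

test_that("cutoff selection is invariant to the ordering of calibrator points", {
  sums <- dplyr::filter(gnas_calibrators(), target_variant == "c.605G>A")
  shuffled <- sums[c(4, 1, 7, 2, 6, 3, 5), ]
  k <- determine_cutoff(calibrator_from_summary(shuffled, gnas_assay("c.605G>A")))
  expect_equal(k$cpm_mean, 0.464)
  expect_equal(k$rma_percent, 1.5)
})

test_that("samples are called against the cutoff mean, zero always wild type", {
  k605 <- determine_cutoff(curve_605())
  expect_equal(call_sample(c(0.815, 0.383, 0), k605), c("MUT", "WT", "WT"))
  expect_equal(call_sample(k605$cpm_mean, k605), "MUT")  # at the cutoff: MUT
  expect_error(call_sample(-0.1, k605), class = "mosaicdpcr_domain_error")
})

test_that("RMA labels follow the log-nearest anchor and 2-SD band rule", {
  c605 <- curve_605()
  # at or above the top point's mean: labelled at the 100% level
  expect_equal(assign_rma(17.626, c605)$label, "100")
  expect_equal(assign_rma(25, c605)$label, "100")
  # exactly on a point mean: "=" that level
  hit <- assign_rma(2.44, c605)
  expect_equal(hit$relation, "=")
  expect_equal(hit$level, 12.5)
  # midway between two anchors, outside both 2-SD bands: ">" the lower level
  toy <- calibrator_from_summary(
    tibble::tibble(rma_percent = c(0, 5, 20),
                   mean_cpm = c(0.01, 1, 4), sd_cpm = c(0.001, 0.01, 0.01),
                   n_reps = 3L),
    gnas_assay("c.605G>A"))
  mid <- assign_rma(1.9, toy)
  expect_equal(mid$relation, ">")
  expect_equal(mid$level, 5)
  expect_equal(mid$label, ">5")
  below <- assign_rma(3.5, toy)
  expect_equal(below$label, "<20")
  # a sample that would not be called mutant has no RMA label
  expect_error(assign_rma(0.1, c605), class = "mosaicdpcr_usage_error")
})

test_that("limit of detection is the ceiling-rounded cutoff mass concentration", {
  expect_equal(compute_lod(determine_cutoff(curve_605())), 0.01)
  expect_equal(compute_lod(determine_cutoff(curve_604())), 0.01)
  # ceiling, not half-up: a cutoff of 3 cpm is 0.0331 ng/ul -> LOD 0.04
  toy <- calibrator_from_summary(
    tibble::tibble(rma_percent = c(0, 50), mean_cpm = c(0.001, 3),
                   sd_cpm = c(0.001, 0.01), n_reps = 3L),
    gnas_assay("c.604C>T"))
  expect_equal(compute_lod(determine_cutoff(toy)), 0.04)
})
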