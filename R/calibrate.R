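#' Printed calibrator summaries for the two GNAS assays
#'
#' Mean, SD and replicate count of the observed reference cpm at each
#' relative-mutation-abundance (RMA) dilution of the heterozygous mutant
#' control series, as reported for the validated assays: the c.604C>T series
#' spans 3-100% RMA, the c.605G>A series 1.5-100%, each with a 0% (wild-type
#' background) point and triplicate chips per dilution.
#'
#' @return A tibble with `assay_id`, `target_variant`, `rma_percent`,
#'   `mean_cpm`, `sd_cpm`, `n_reps`.
#' @examples
#' gnas_calibrators()
#' @export
gnas_calibrators <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      assay_id = "GNAS_27887_mu", target_variant = "c.604C>T",
      rma_percent = c(0, 3, 6, 12.5, 25, 50, 100),
      mean_cpm = c(0.102, 0.391, 0.563, 1.321, 3.035, 6.855, 12.11),
      sd_cpm   = c(0.017, 0.074, 0.052, 0.157, 0.411, 0.494, 0.023)
    ),
    tibble::tibble(
      assay_id = "GNAS_27895_mu", target_variant = "c.605G>A",
      rma_percent = c(0, 1.5, 3, 6, 12.5, 25, 100),
      mean_cpm = c(0.068, 0.464, 0.976, 1.171, 2.44, 5.17, 17.47),
      sd_cpm   = c(0.06, 0.012, 0.189, 0.181, 0.346, 0.873, 0.177)
    )
  ) |>
    dplyr::mutate(n_reps = 3L)
}

new_calibrator_curve <- function(points, assay) {
  points <- dplyr::arrange(points, .data$rma_percent)
  if (sum(points$rma_percent == 0) != 1L) {
    stop_input("A calibrator curve needs exactly one 0% RMA point.",
               "mosaicdpcr_config_error")
  }
  if (any(points$n_reps < 2L)) {
    stop_input("Every calibrator point needs at least 2 replicates.",
               "mosaicdpcr_config_error")
  }
  if (any(points$sd_cpm < 0)) {
    stop_input("Calibrator SDs must be non-negative.", "mosaicdpcr_config_error")
  }
  if (is.unsorted(points$mean_cpm)) {
    rlang::warn("Calibrator mean cpm is not non-decreasing in RMA.",
                class = "mosaicdpcr_monotonicity_warning")
  }
  structure(points,
            assay = assay,
            class = c("calibrator_curve", class(tibble::tibble())))
}

#' Build a calibrator curve from replicate cpm measurements
#'
#' Summarises replicate chips per dilution to per-point mean and sample SD
#' (n - 1 denominator) and orders points by ascending RMA. A 0% dilution
#' (wild-type background) must be present; it anchors cutoff selection.
#'
#' @param replicates A data frame with columns `rma_percent` and `cpm`, one
#'   row per replicate chip (at least two per dilution).
#' @param assay A one-row assay definition, see [gnas_assay()].
#' @return A tibble of class `calibrator_curve` with columns `rma_percent`,
#'   `mean_cpm`, `sd_cpm`, `n_reps`.
#' @examples
#' reps <- tibble::tibble(
#'   rma_percent = rep(c(0, 3), each = 3),
#'   cpm = c(0.09, 0.10, 0.11, 0.38, 0.39, 0.40)
#' )
#' build_calibrator(reps, gnas_assay("c.604C>T"))
#' @export
build_calibrator <- function(replicates, assay) {
  if (!all(c("rma_percent", "cpm") %in% names(replicates))) {
    stop_input("`replicates` needs `rma_percent` and `cpm` columns.",
               "mosaicdpcr_config_error")
  }
  points <- replicates |>
    dplyr::group_by(.data$rma_percent) |>
    dplyr::summarise(
      mean_cpm = mean(.data$cpm),
      sd_cpm = stats::sd(.data$cpm),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
  new_calibrator_curve(points, assay)
}

#' Build a calibrator curve directly from printed summaries
#'
#' @param summaries A data frame with `rma_percent`, `mean_cpm`, `sd_cpm` and
#'   `n_reps` (e.g. one assay's rows of [gnas_calibrators()]).
#' @inheritParams build_calibrator
#' @return A `calibrator_curve`, as from [build_calibrator()].
#' @examples
#' sums <- dplyr::filter(gnas_calibrators(), target_variant == "c.605G>A")
#' calibrator_from_summary(sums, gnas_assay("c.605G>A"))
#' @export
calibrator_from_summary <- function(summaries, assay) {
  need <- c("rma_percent", "mean_cpm", "sd_cpm", "n_reps")
  if (!all(need %in% names(summaries))) {
    stop_input(sprintf("`summaries` needs columns %s.", paste(need, collapse = ", ")),
               "mosaicdpcr_config_error")
  }
  new_calibrator_curve(dplyr::select(tibble::as_tibble(summaries),
                                     dplyr::all_of(need)), assay)
}

#' Two-sample t-test from summary statistics
#'
#' Student's (pooled-variance) or Welch's two-sample t-test computed from
#' group means, SDs and sizes, two-sided. When both SDs are zero the test
#' degenerates: p = 0 if the means differ, 1 otherwise.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param var_equal Pool the variances (`TRUE`, the default, reproducing the
#'   reported calibrator p-values) or use the Welch-Satterthwaite
#'   approximation.
#' @return A one-row tibble: `estimate` (mean1 - mean2), `statistic`, `df`,
#'   `p_value`.
#' @examples
#' summary_t_test(0.464, 0.012, 3, 0.068, 0.06, 3)  # p ~ 0.0004
#' @export
summary_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  if (min(n1, n2) < 2) {
    stop_input("Both groups need n >= 2.", "mosaicdpcr_domain_error")
  }
  diff <- mean1 - mean2
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else n1 + n2 - 2
  }
  if (se == 0) {
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    stat <- diff / se
    p <- 2 * stats::pt(-abs(stat), df)
  }
  tibble::tibble(estimate = diff, statistic = stat, df = df, p_value = p)
}

#' Select the positivity cutoff from a calibrator curve
#'
#' Each nonzero-RMA calibrator point is tested against the 0% point with a
#' two-sided two-sample t-test from summary statistics; the cutoff is the
#' lowest-RMA nonzero point significant at `alpha`. Its mean cpm becomes the
#' sample positivity threshold. If no point separates from background the
#' assay is not validated and an error is raised.
#'
#' @param curve A `calibrator_curve`.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Passed to [summary_t_test()].
#' @return A one-row tibble of class `dpcr_cutoff`: `rma_percent`, `cpm_mean`,
#'   `cpm_sd`, `statistic`, `df`, `p_value`.
#' @examples
#' curve <- calibrator_from_summary(
#'   dplyr::filter(gnas_calibrators(), target_variant == "c.604C>T"),
#'   gnas_assay("c.604C>T"))
#' determine_cutoff(curve)  # 0.391 at 3% RMA
#' @export
determine_cutoff <- function(curve, alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(curve, "calibrator_curve"))
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  zero <- curve[curve$rma_percent == 0, ]
  nonzero <- dplyr::arrange(curve[curve$rma_percent > 0, ], .data$rma_percent)
  tests <- purrr::pmap_dfr(
    nonzero[c("mean_cpm", "sd_cpm", "n_reps")],
    function(mean_cpm, sd_cpm, n_reps) {
      summary_t_test(mean_cpm, sd_cpm, n_reps,
                     zero$mean_cpm, zero$sd_cpm, zero$n_reps,
                     var_equal = var_equal)
    }
  )
  hit <- which(tests$p_value < alpha & nonzero$mean_cpm > zero$mean_cpm)
  if (length(hit) == 0L) {
    stop_input("No calibrator point separates from the 0% background; assay not validated.",
               "mosaicdpcr_no_cutoff_error")
  }
  i <- hit[1]
  out <- tibble::tibble(
    rma_percent = nonzero$rma_percent[i],
    cpm_mean = nonzero$mean_cpm[i],
    cpm_sd = nonzero$sd_cpm[i],
    statistic = tests$statistic[i],
    df = tests$df[i],
    p_value = tests$p_value[i]
  )
  structure(out,
            assay = attr(curve, "assay", exact = TRUE),
            alpha = alpha,
            class = c("dpcr_cutoff", class(tibble::tibble())))
}

#' Call a sample mutant or wild type against a cutoff
#'
#' Deterministic point-cutoff rule: a sample is MUT when its cpm is at or
#' above the cutoff mean, WT otherwise. This replaces the partly manual
#' error-bar examination of instrument review with a reproducible rule; on
#' the packaged cohort it reproduces 157 of 158 recorded per-variant calls,
#' the single discordance being a documented borderline sample sitting 0.021
#' cpm above the c.604T cutoff yet reviewed as WT.
#'
#' @param cpm Mutant copies per ul (vectorised, each element >= 0).
#' @param cutoff A `dpcr_cutoff` from [determine_cutoff()].
#' @return Character vector of `"MUT"` / `"WT"`.
#' @examples
#' curve <- calibrator_from_summary(
#'   dplyr::filter(gnas_calibrators(), target_variant == "c.605G>A"),
#'   gnas_assay("c.605G>A"))
#' call_sample(c(0.815, 0.383), determine_cutoff(curve))
#' @export
call_sample <- function(cpm, cutoff) {
  stopifnot(inherits(cutoff, "dpcr_cutoff"))
  if (!is.numeric(cpm) || anyNA(cpm) || any(cpm < 0)) {
    stop_input("`cpm` must be non-negative and non-missing.",
               "mosaicdpcr_domain_error")
  }
  ifelse(cpm >= cutoff$cpm_mean, "MUT", "WT")
}

#' Assign an RMA category label to a positive sample
#'
#' Anchors the sample to the calibrator dilution whose mean cpm is nearest on
#' the log scale, then labels it `"="` that level when within two SDs of the
#' anchor mean, `">"` / `"<"` otherwise according to the side it falls on. A
#' cpm at or above the top point's mean is labelled at the top level (100%).
#' The instrument subcluster attribution this emulates is not fully
#' deterministic, so labels are descriptive rather than validated calls.
#'
#' @param cpm A single cpm value of a sample already called MUT.
#' @param curve A `calibrator_curve`.
#' @return A one-row tibble: `relation` (one of `"="`, `"<"`, `">"`), `level`
#'   (the anchoring RMA percent) and `label` (e.g. `">6"`, `"<12.5"`,
#'   `"100"`).
#' @examples
#' curve <- calibrator_from_summary(
#'   dplyr::filter(gnas_calibrators(), target_variant == "c.605G>A"),
#'   gnas_assay("c.605G>A"))
#' assign_rma(17.626, curve)  # "100"
#' @export
assign_rma <- function(cpm, curve) {
  stopifnot(inherits(curve, "calibrator_curve"))
  check_number(cpm, "cpm", min = 0)
  nonzero <- curve[curve$rma_percent > 0, ]
  if (cpm < min(nonzero$mean_cpm)) {
    stop_input("`assign_rma()` is only defined for samples called MUT.",
               "mosaicdpcr_usage_error")
  }
  top <- nonzero[which.max(nonzero$rma_percent), ]
  if (cpm >= top$mean_cpm) {
    return(tibble::tibble(relation = "=", level = top$rma_percent,
                          label = format_rma("=", top$rma_percent)))
  }
  i <- which.min(abs(log(cpm) - log(nonzero$mean_cpm)))
  anchor <- nonzero[i, ]
  relation <- if (abs(cpm - anchor$mean_cpm) <= 2 * anchor$sd_cpm) {
    "="
  } else if (cpm > anchor$mean_cpm) ">" else "<"
  tibble::tibble(relation = relation, level = anchor$rma_percent,
                 label = format_rma(relation, anchor$rma_percent))
}

format_rma <- function(relation, level) {
  lvl <- format(level, trim = TRUE)
  if (relation == "=") lvl else paste0(relation, lvl)
}

#' Limit of detection in ng/ul
#'
#' The smallest reportable mass concentration distinguishable from wild type:
#' the absolute quantification of the cutoff mean cpm, rounded up (ceiling)
#' to two decimals. Rounding up, not half-up, because a limit of detection
#' must never be reported below the concentration actually resolved; under
#' this rule both validated assays yield the single reported LOD of
#' 0.01 ng/ul.
#'
#' @param cutoff A `dpcr_cutoff`.
#' @param constants A [quant_constants()].
#' @return ng/ul, two decimals.
#' @export
compute_lod <- function(cutoff, constants = quant_constants()) {
  stopifnot(inherits(cutoff, "dpcr_cutoff"))
  ceiling_digits(cutoff$cpm_mean * constants$genome_mass_ng *
                   constants$dilution_factor, 2)
}
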