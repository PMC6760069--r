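# ggplot2 displays for chips and calibrator curves.

#' Scatterplot of a chip's wells
#'
#' Mirrors the instrument's raw-data view: FAM signal per well, with the
#' assay's RFU threshold drawn and wells coloured by their classification
#' (positive / negative / QC-failed).
#'
#' @param object A `chip_data` tibble.
#' @param policy A [qc_policy()] used for the QC colouring.
#' @param ... Ignored.
#' @return A ggplot object.
#' @examples
#' autoplot(simulate_chip(sim_params(het_cell_fraction = 0.25, seed = 1)))
#' @method autoplot chip_data
#' @export
autoplot.chip_data <- function(object, policy = qc_policy(), ...) {
  assay <- chip_assay(object)
  thr <- assay$rfu_threshold
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$quality <= policy$min_quality ~ "QC fail",
      .data$fam_rfu > thr ~ "positive",
      TRUE ~ "negative"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$well_index, .data$fam_rfu,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#fdb863",
                                            `QC fail` = "grey70")) +
    ggplot2::labs(x = "well", y = "FAM signal (RFU)", colour = NULL,
                  title = sprintf("%s (%s)", assay$assay_id, assay$target_variant),
                  subtitle = sprintf("threshold %g RFU", thr)) +
    ggplot2::theme_minimal()
}

#' Calibrator curve with error bars
#'
#' Mean cpm (+/- SD) per RMA dilution on a log cpm scale, with the selected
#' positivity cutoff drawn when supplied.
#'
#' @param object A `calibrator_curve`.
#' @param cutoff Optional `dpcr_cutoff` to draw as a horizontal line.
#' @param ... Ignored.
#' @return A ggplot object.
#' @examples
#' curve <- calibrator_from_summary(
#'   dplyr::filter(gnas_calibrators(), target_variant == "c.605G>A"),
#'   gnas_assay("c.605G>A"))
#' autoplot(curve, cutoff = determine_cutoff(curve))
#' @method autoplot calibrator_curve
#' @export
autoplot.calibrator_curve <- function(object, cutoff = NULL, ...) {
  assay <- attr(object, "assay", exact = TRUE)
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(rma = factor(paste0(.data$rma_percent, "%"),
                               levels = paste0(sort(.data$rma_percent), "%")))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rma, .data$mean_cpm)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_cpm - .data$sd_cpm, 1e-3),
                                        ymax = .data$mean_cpm + .data$sd_cpm),
                           width = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative mutation abundance", y = "cpm (copies/ul)",
                  title = if (!is.null(assay)) {
                    sprintf("Calibrator curve, %s", assay$target_variant)
                  }) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff$cpm_mean,
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' @rdname autoplot.calibrator_curve
#' @param curve A `calibrator_curve` (data-frame-first alias of the autoplot
#'   method).
#' @export
plot_calibrator <- function(curve, cutoff = NULL, ...) {
  autoplot.calibrator_curve(curve, cutoff = cutoff, ...)
}

#' Detection rates per tissue class and method
#'
#' Bar panel comparing the four methods over the tissue classes of a cohort.
#'
#' @param records A `gnas_cohort` from [load_cohort()].
#' @param round_mode Passed to [detection_table()].
#' @return A ggplot object.
#' @export
plot_detection_rates <- function(records, round_mode = "half_up") {
  tabs <- purrr::map_dfr(COHORT_METHODS, function(m) {
    tibble::as_tibble(detection_table(records, m, round_mode)) |>
      dplyr::mutate(method = m)
  }) |>
    dplyr::filter(!.data$group %in% c("All samples", "Patients")) |>
    dplyr::mutate(group = factor(.data$group, levels = TISSUE_CLASSES),
                  method = factor(.data$method, levels = COHORT_METHODS))
  ggplot2::ggplot(tabs, ggplot2::aes(.data$group, .data$rate, fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "detection rate (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
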