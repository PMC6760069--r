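# broom-style accessors for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calibrator curve
#'
#' @param x A `calibrator_curve`.
#' @param ... Ignored.
#' @return One row per dilution point: `rma_percent`, `mean_cpm`, `sd_cpm`,
#'   `n_reps`.
#' @method tidy calibrator_curve
#' @export
tidy.calibrator_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-line summary of a calibrator curve
#'
#' @param x A `calibrator_curve`.
#' @param ... Ignored.
#' @return A one-row tibble: assay identity, number of points, RMA range and
#'   whether the mean cpm is monotone in RMA.
#' @method glance calibrator_curve
#' @export
glance.calibrator_curve <- function(x, ...) {
  assay <- attr(x, "assay", exact = TRUE)
  tibble::tibble(
    assay_id = if (is.null(assay)) NA_character_ else assay$assay_id,
    target_variant = if (is.null(assay)) NA_character_ else assay$target_variant,
    n_points = nrow(x),
    rma_min = min(x$rma_percent),
    rma_max = max(x$rma_percent),
    monotone = !is.unsorted(x$mean_cpm)
  )
}

#' Tidy a positivity cutoff
#'
#' @param x A `dpcr_cutoff`.
#' @param ... Ignored.
#' @return A one-row tibble with the cutoff point and its test statistics.
#' @method tidy dpcr_cutoff
#' @export
tidy.dpcr_cutoff <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-line summary of a positivity cutoff
#'
#' @param x A `dpcr_cutoff`.
#' @param ... Ignored.
#' @return A one-row tibble with the assay, cutoff cpm, its RMA level, the
#'   test p-value and the significance level used.
#' @method glance dpcr_cutoff
#' @export
glance.dpcr_cutoff <- function(x, ...) {
  assay <- attr(x, "assay", exact = TRUE)
  tibble::tibble(
    assay_id = if (is.null(assay)) NA_character_ else assay$assay_id,
    cutoff_cpm = x$cpm_mean,
    rma_percent = x$rma_percent,
    p_value = x$p_value,
    alpha = attr(x, "alpha", exact = TRUE)
  )
}
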