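# broom-style verbs and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ROC calibration
#'
#' @param x A `roc_calibration` from [calibrate_cutoff()].
#' @param ... Unused.
#' @return The full ROC curve as a tibble with a `metric` column.
#' @method tidy roc_calibration
#' @export
tidy.roc_calibration <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$curve), metric = x$metric, .before = 1)
}

#' One-row summary of an ROC calibration
#'
#' @inheritParams tidy.roc_calibration
#' @return One-row tibble: `metric`, `min_tpr`, selected `cutoff`, `tpr`,
#'   `fpr` and the confusion counts at that cutoff.
#' @method glance roc_calibration
#' @export
glance.roc_calibration <- function(x, ...) {
  dplyr::mutate(x$selected, metric = x$metric, min_tpr = x$min_tpr,
                .before = 1)
}

#' Plot an ROC calibration
#'
#' ROC curve over the cutoff grid with the selected operating point
#' marked and the TPR floor drawn as a dashed line.
#'
#' @param object A `roc_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_calibration
#' @export
autoplot.roc_calibration <- function(object, ...) {
  curve <- tibble::as_tibble(object$curve)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_hline(yintercept = object$min_tpr, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(data = object$selected, colour = "red", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (%s cutoffs); selected cutoff %.3g",
                      object$metric, object$selected$cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Plot candidate score distributions for a set of queries
#'
#' Histograms of percentile and quotient values over all candidates,
#' faceted by metric — useful for seeing the uniform-vs-right-skewed
#' contrast that makes quotient cutoffs more effective.
#'
#' @param results Candidate table from [match_spectra()].
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(results) {
  long <- tibble::as_tibble(results) |>
    dplyr::mutate(quotient_pct = 100 * .data$quotient) |>
    tidyr::pivot_longer(c("percentile", "quotient_pct"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         quotient_pct = "quotient (x100)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 25, boundary = 0) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "candidate metric value", y = "candidates") +
    ggplot2::theme_minimal()
}
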