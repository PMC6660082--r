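#' Plot per-assay reference intervals
#'
#' Mean-centred 95% reference intervals per assay on the delta-Ct (log2)
#' scale, one panel per normalization scheme, ordered by fold span.
#'
#' @param report A `study_report` from [run_study()].
#' @return A ggplot object.
#' @export
plot_reference_intervals <- function(report) {
  stopifnot(inherits(report, "study_report"))
  d <- report$assays |>
    dplyr::mutate(
      assay_id = stats::reorder(.data$assay_id, .data$fold_total),
      lo = .data$lower_dct - .data$mean_dct,
      hi = .data$upper_dct - .data$mean_dct
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$assay_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.4) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean-centred ΔCt (log2 expression)",
                  title = "95% reference intervals by assay") +
    ggplot2::theme_minimal()
}

#' Plot the variance-component split per assay
#'
#' Stacked percentage of total variance attributed to between- and
#' within-donor sources, per assay and scheme.
#'
#' @param report A `study_report` from [run_study()].
#' @return A ggplot object.
#' @export
plot_variance_components <- function(report) {
  stopifnot(inherits(report, "study_report"))
  d <- report$assays |>
    dplyr::select("assay_id", "scheme", "percent_between", "percent_within") |>
    tidyr::pivot_longer(c("percent_between", "percent_within"),
                        names_to = "component", values_to = "percent") |>
    dplyr::mutate(component = sub("percent_", "", .data$component))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$assay_id, y = .data$percent,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of total variance",
                  title = "Between- vs within-donor variance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for study reports
#'
#' @param object A `study_report`.
#' @param type `"intervals"` or `"components"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, type = c("intervals", "components"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
         intervals = plot_reference_intervals(object),
         components = plot_variance_components(object))
}
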