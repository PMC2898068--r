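# ggplot2 views of stratified results.

#' Plot sensitivity and specificity across strata
#'
#' For expression strata the x axis is the bin's upper expression edge on a
#' log scale; for lane curves it is the cumulative lane count; otherwise the
#' stratum label.
#'
#' @param object A `stratum_tbl` (e.g. from [stratify_by_expression()] or
#'   [lane_accumulation_curve()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stratum_tbl
#' @export
autoplot.stratum_tbl <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(
      c("sensitivity", "specificity"),
      names_to = "measure", values_to = "value"
    )
  if ("expr_hi" %in% names(object)) {
    x <- pmin(long$expr_hi, 100)
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = x, y = .data$value, colour = .data$measure
    )) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "expression (% of most expressed transcript)")
  } else if ("lanes" %in% names(object)) {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$lanes, y = .data$value, colour = .data$measure
    )) +
      ggplot2::labs(x = "cumulative lanes of sequence data")
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$stratum, y = .data$value, fill = .data$measure
    )) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = NULL)
    return(p + ggplot2::ylim(0, 1))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, colour = NULL)
}

#' True positives recovered per cumulative lane
#'
#' @param curve A `stratum_tbl` from [lane_accumulation_curve()].
#' @return A ggplot object.
#' @export
plot_lane_tp <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lanes, y = .data$tp)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "cumulative lanes of sequence data",
      y = "true positive SNVs identified"
    )
}

#' Histogram of per-exon mean coverage
#'
#' @param covs Output of [exon_mean_coverage()].
#' @param threshold Coverage-adequacy threshold to mark (default 5).
#' @return A ggplot object.
#' @export
plot_exon_coverage <- function(covs, threshold = 5) {
  ggplot2::ggplot(covs, ggplot2::aes(x = .data$mean_coverage + 0.5)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "mean exon coverage (reads/base, +0.5)", y = "exons")
}
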