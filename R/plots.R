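# ggplot2 views of the result objects.

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Bars run from the incremental total cost at each parameter's low bound to
#' the incremental at its high bound, ordered by span; the solid green line
#' marks no economic impact (zero incremental cost) and the dashed grey line
#' the base-case incremental.
#'
#' @param object A `bim_dsa` from [one_way_dsa()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bim_dsa <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$span)
  df$parameter <- factor(df$parameter, levels = df$parameter)
  base_incr <- attr(object, "base_incremental")
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_vline(xintercept = 0, colour = "darkgreen") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$incremental_at_low,
                   xend = .data$incremental_at_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 4, colour = "steelblue", lineend = "butt"
    ) +
    ggplot2::labs(
      x = "Incremental annual cost (GBP, intervention - reference)",
      y = NULL,
      title = "One-way deterministic sensitivity analysis"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(base_incr)) {
    p <- p + ggplot2::geom_vline(xintercept = base_incr, colour = "grey50",
                                 linetype = "dashed")
  }
  p
}

#' Cost comparison plot for a model report
#'
#' Stacked annual cost components per arm.
#'
#' @param object A `bim_report` from [bim_run()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bim_report <- function(object, ...) {
  components <- c("nurse_cost", "surgeon_cost", "drug_acquisition_cost",
                  "rescue_cost")
  df <- tidyr::pivot_longer(
    object$costs[, c("arm", components)],
    -"arm", names_to = "component", values_to = "cost"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$cost,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Annual cost (GBP)",
                  title = "Annual cost comparison by arm") +
    ggplot2::theme_minimal()
}
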