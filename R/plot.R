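#' Odds-ratio plot of significant findings
#'
#' One dot per significant phecode at its odds-ratio point estimate with a
#' segment for the confidence interval, on a log-scaled OR axis; a gray band
#' spans the null interval; each finding is coloured by, and annotated with,
#' its Novelty Finding Index on the fixed `[0, 10]` scale. When nothing is
#' significant the plot shows the band with a notice.
#'
#' @param results Output of [add_sgpv()] / [add_novelty()] /
#'   [run_pipeline()].
#' @param null A [null_interval()]; taken from the results' attribute when
#'   omitted.
#' @return A ggplot object.
#' @export
render_or_plot <- function(results, null = NULL) {
  null <- null %||% attr(results, "null_interval")
  if (is.null(null)) stop("no null interval supplied or attached", call. = FALSE)
  null <- as_null_interval(null)
  if (nrow(results) == 0) stop("no results to plot", call. = FALSE)

  sig <- results |>
    dplyr::filter(!is.na(.data$p_delta), .data$p_delta == 0)
  if (!"nfi" %in% names(sig)) sig$nfi <- NA_real_

  band <- ggplot2::annotate("rect", xmin = null$or[1], xmax = null$or[2],
                            ymin = -Inf, ymax = Inf,
                            fill = "gray70", alpha = 0.5)
  base <- ggplot2::ggplot() + band +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  colour = "NFI") +
    ggplot2::theme_minimal()

  if (nrow(sig) == 0) {
    return(base +
             ggplot2::annotate("text", x = sqrt(prod(null$or)), y = 0,
                               label = "no significant findings") +
             ggplot2::scale_y_continuous(breaks = NULL))
  }
  sig <- sig |>
    dplyr::arrange(.data$or) |>
    dplyr::mutate(phecode = factor(.data$phecode, levels = .data$phecode),
                  nfi_label = ifelse(is.na(.data$nfi), "",
                                     sprintf("%.2f", .data$nfi)))
  base +
    ggplot2::geom_segment(
      data = sig,
      ggplot2::aes(x = .data$or_lo, xend = .data$or_hi,
                   y = .data$phecode, yend = .data$phecode,
                   colour = .data$nfi)
    ) +
    ggplot2::geom_point(
      data = sig,
      ggplot2::aes(x = .data$or, y = .data$phecode, colour = .data$nfi),
      size = 2
    ) +
    ggplot2::geom_text(
      data = sig,
      ggplot2::aes(x = .data$or_hi, y = .data$phecode,
                   label = .data$nfi_label),
      hjust = -0.2, vjust = -0.4, size = 3
    ) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 10), na.value = "gray40")
}

#' @rdname render_or_plot
#' @param object A `phescreen_results` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.phescreen_results <- function(object, ...) {
  render_or_plot(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
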