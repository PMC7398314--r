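# Optional ggplot2 figures (ggplot2 is suggested, not required).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the CSV exports",
         call. = FALSE)
  }
}

#' Tornado diagram for one technique
#'
#' Horizontal bars spanning the ICER range of each swept parameter, widest
#' on top, with a vertical line at the base-case ICER.
#'
#' @param x A [tornado()] result.
#' @return A ggplot object.
#' @export
plot_tornado <- function(x) {
  stopifnot(inherits(x, "tornado_result"))
  .need_ggplot()
  d <- as.data.frame(x)
  d$label <- factor(d$label, levels = rev(d$label))
  d$lo <- pmin(d$icer_low, d$icer_high)
  d$hi <- pmax(d$icer_low, d$icer_high)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       y = label, yend = label),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = d$icer_base[1], linetype = "dashed") +
    ggplot2::labs(x = "ICER vs SOC ($/QALY)", y = NULL,
                  title = paste(attr(x, "strategy"), "vs SOC")) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' Probability of being more cost-effective than SOC as a function of the
#' willingness-to-pay threshold, with dashed guides at $50,000 and
#' $100,000 per QALY.
#'
#' @param x A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x) {
  stopifnot(inherits(x, "ceac_curve"))
  .need_ggplot()
  d <- as.data.frame(x)
  ggplot2::ggplot(d, ggplot2::aes(x = wtp, y = probability,
                                  colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(50000, 100000), linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "P(more cost-effective than SOC)") +
    ggplot2::theme_minimal()
}
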