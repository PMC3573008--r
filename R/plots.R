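#' Grouped bar chart of responsive-gene ratios
#'
#' Renders the long-format `ratios` table of [run_profile()] as grouped
#' bars: one panel per sex, bars for the four ratio types per condition
#' (and time point). Requires ggplot2.
#'
#' @param ratios The `ratios` data.frame of [run_profile()].
#' @return A ggplot object.
#' @export
plot_responsive_ratios <- function(ratios) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_responsive_ratios needs the ggplot2 package", call. = FALSE)
  d <- ratios
  d$contrast <- ifelse(is.na(d$time_point), d$condition,
                       paste0(d$condition, "@", d$time_point))
  d$ratio_type <- factor(d$ratio_type, levels = c(
    "r_up_male_biased", "r_down_male_biased",
    "r_up_female_biased", "r_down_female_biased"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$contrast, y = .data$ratio, fill = .data$ratio_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(~sex, ncol = 1) +
    ggplot2::labs(x = NULL, y = "responsive-gene ratio",
                  fill = "ratio") +
    ggplot2::theme_minimal()
}
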