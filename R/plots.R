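# Optional figures (ggplot2 is suggested, not required).

#' Plot the ALPS distribution by group
#'
#' Box-and-jitter plot of the bilateral ALPS index across cohort groups,
#' the standard figure accompanying the covariate-adjusted group
#' comparison.
#'
#' @param cohort an `alps_cohort` data frame.
#' @param grouping grouping column (default `"group"`; use `"stage4"`
#'   after [add_stage4()] for the stage-level view).
#' @return A ggplot object.
#' @export
plot_alps_groups <- function(cohort, grouping = "group") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_alps_groups requires the ggplot2 package", call. = FALSE)
  d <- as.data.frame(cohort)
  d[[grouping]] <- factor(d[[grouping]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[grouping]], y = .data[["alps"]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "DTI-ALPS (bilateral mean)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
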