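# Plot methods for the main result types. The pipeline itself emits
# plot-ready tables; these helpers render the conventional displays.

#' Scatter plot of a harmonized dataset with fitted MR slopes
#'
#' SNP outcome betas against exposure betas with the IVW (through-origin) and
#' MR-Egger (free-intercept) fits overlaid.
#'
#' @param object an `mr_harmonized` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mr_harmonized
#' @export
autoplot.mr_harmonized <- function(object, ...) {
  ivw <- mr_ivw(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$beta_exposure, y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_outcome - .data$se_outcome,
                                        ymax = .data$beta_outcome + .data$se_outcome),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta, colour = "steelblue") +
    ggplot2::labs(x = "SNP effect on exposure (SD)",
                  y = "SNP effect on outcome (log-odds)",
                  title = sprintf("%s: IVW slope %.3f",
                                  attr(object, "exposure_id") %||% "", ivw$beta))
  if (nrow(object) >= 3) {
    eg <- mr_egger(object)
    p <- p + ggplot2::geom_abline(intercept = eg$intercept, slope = eg$beta,
                                  colour = "firebrick", linetype = 2)
  }
  p
}

#' Funnel plot of per-SNP ratio estimates
#'
#' @param data the tibble from [funnel_data()] (or a harmonized dataset, in
#'   which case the table is computed first).
#' @param center optional pooled estimate to draw as a vertical line.
#' @return a ggplot.
#' @export
plot_funnel <- function(data, center = NULL) {
  if (!all(c("ratio", "precision") %in% names(data))) data <- funnel_data(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Per-SNP causal estimate (Wald ratio)",
                  y = expression(Precision ~ (1 / SE)))
  if (!is.null(center)) p <- p + ggplot2::geom_vline(xintercept = center, linetype = 2)
  p
}

#' Leave-one-out forest plot
#'
#' @param data the tibble from [mr_leave_one_out()].
#' @return a ggplot with one row per dropped SNP, flagged SNPs highlighted.
#' @export
plot_leave_one_out <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$beta, y = .data$snp_id,
                                     colour = .data$flag)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "IVW estimate excluding the SNP", y = NULL)
}

#' MIP / MACE summary plot for a model-averaging result
#'
#' @param object an `mr_bma_result`.
#' @param ... unused.
#' @return a ggplot of marginal inclusion probabilities, coloured by the
#'   sign of the model-averaged causal effect.
#' @method autoplot mr_bma_result
#' @export
autoplot.mr_bma_result <- function(object, ...) {
  d <- dplyr::mutate(object$exposures,
                     direction = ifelse(.data$mace >= 0, "positive", "negative"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mip,
                                  y = stats::reorder(.data$exposure_id, .data$mip),
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Marginal inclusion probability", y = NULL,
                  fill = "MACE sign")
}

#' Forest plot across exposures and methods
#'
#' @param results the `results` tibble from [mr_run_forward()] (needs
#'   `exposure_id`, `method`, `or_`, `or_low`, `or_high`).
#' @return a ggplot on the odds-ratio scale.
#' @export
plot_forest <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$or_, y = .data$exposure_id,
                                        colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low, xmax = .data$or_high),
                            height = 0.2,
                            position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per 1 SD of exposure (95% CI)", y = NULL)
}
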