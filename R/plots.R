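# ggplot2 views of cohorts and results.

roi_label <- function(roi) {
  labs <- c(whole_brainstem = "Whole brainstem", medulla = "Medulla",
            pons = "Pons", midbrain = "Midbrain", cerebrum = "Cerebrum")
  factor(labs[roi], levels = unname(labs))
}

#' Scatterplots of regional volume against ICV or age
#'
#' One panel per analysis ROI, with per-sex least-squares lines when plotting
#' against ICV (the sex-by-ICV interaction the model tests for is visible as
#' non-parallel lines) and a pooled line against age.
#'
#' @param data A cohort table.
#' @param x `"icv"` or `"age"`.
#' @return A ggplot object.
#' @export
plot_volume_relationships <- function(data, x = c("icv", "age")) {
  x <- match.arg(x)
  data <- validate_cohort(data)
  long <- tidyr::pivot_longer(data, cols = dplyr::all_of(enhv_rois()),
                              names_to = "roi", values_to = "volume")
  long$roi <- roi_label(long$roi)
  long$sex_label <- factor(ifelse(long$sex == 1, "male", "female"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$volume))
  if (x == "icv") {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$sex_label),
                          alpha = 0.6, size = 1) +
      ggplot2::geom_smooth(ggplot2::aes(colour = .data$sex_label),
                           method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.6)
  } else {
    p <- p +
      ggplot2::geom_point(alpha = 0.6, size = 1) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.6, colour = "black")
  }
  p +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = if (x == "icv") "ICV (mm³)" else "Age (years)",
                  y = "Volume (mm³)", colour = "Sex") +
    ggplot2::theme_minimal()
}

#' Forest plot of ICC validation results
#'
#' ICC point estimates with 95% confidence intervals per ROI, with the
#' reliability band cut points (0.4, 0.6, 0.75) and the validity threshold
#' (ICC > 0.4) marked.
#'
#' @param object An `enhv_validation` from [validate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enhv_validation
#' @export
autoplot.enhv_validation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$roi <- roi_label(df$roi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$roi)) +
    ggplot2::geom_vline(xintercept = c(0.4, 0.6, 0.75), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0.4, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$band), size = 2.5) +
    ggplot2::labs(x = "ICC(A,1) with 95% CI", y = NULL, colour = "Band") +
    ggplot2::theme_minimal()
}

#' Boxplots of ENHV-adjusted volumes by group
#'
#' @param adjusted Long adjusted-volume table from [adjust_volumes()] with a
#'   `group_label` column (bind patient and control tables together first).
#' @return A ggplot object.
#' @export
plot_adjusted_volumes <- function(adjusted) {
  if (!"group_label" %in% names(adjusted)) {
    abort("Adjusted table needs a group_label column.",
          class = "enhv_validation_error")
  }
  adjusted$roi <- roi_label(adjusted$roi)
  ggplot2::ggplot(adjusted,
                  ggplot2::aes(x = .data$roi, y = .data$adjusted,
                               fill = .data$group_label)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.8, position = "dodge") +
    ggplot2::labs(x = NULL, y = "ENHV-adjusted volume (% of ENHV)",
                  fill = "Group") +
    ggplot2::theme_minimal()
}

#' Scatterplots of PTA duration against ENHV-adjusted volume
#'
#' One panel per ROI with a least-squares trend line; annotate with the
#' output of [pta_correlation()] as needed.
#'
#' @param adjusted Long adjusted-volume table for a patient group carrying
#'   `pta_weeks`.
#' @return A ggplot object.
#' @export
plot_pta_correlation <- function(adjusted) {
  if (!"pta_weeks" %in% names(adjusted)) {
    abort("Adjusted table needs a pta_weeks column.",
          class = "enhv_validation_error")
  }
  adjusted$roi <- roi_label(adjusted$roi)
  ggplot2::ggplot(adjusted,
                  ggplot2::aes(x = .data$pta_weeks, y = .data$adjusted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "PTA duration (weeks)",
                  y = "ENHV-adjusted volume (% of ENHV)") +
    ggplot2::theme_minimal()
}
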