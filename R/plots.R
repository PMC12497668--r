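# Figures: method box plot, ICC profile with agreement reference lines,
# Bland-Altman scatter.

#' Box plot of pooled ALPS indices per method
#'
#' Pools subjects, hemispheres and configurations per method; the mean is
#' marked with a cross, outliers follow the 1.5 IQR rule.
#'
#' @param results Results tibble (e.g. `study$results`).
#' @return A ggplot.
#' @export
plot_alps_distribution <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$method, y = .data$index)) +
    ggplot2::geom_boxplot(outlier.colour = "red", outlier.shape = 3) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "ALPS index",
                  title = "ALPS index, both hemispheres and all ROI configurations") +
    ggplot2::theme_minimal()
}

#' Inter-method ICC per ROI configuration
#'
#' Points (with the F-based confidence interval when present) per
#' configuration, with the good-agreement threshold 0.75 as a solid
#' reference line and the poor-agreement threshold 0.5 as a red dashed
#' line.
#'
#' @param table3 Tibble with `config`, `icc` and optionally `ci_lower`,
#'   `ci_upper` (e.g. `study$table3`).
#' @return A ggplot.
#' @export
plot_icc_profile <- function(table3) {
  p <- ggplot2::ggplot(table3, ggplot2::aes(x = .data$config, y = .data$icc,
                                            group = 1)) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "solid") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point()
  if (all(c("ci_lower", "ci_upper") %in% names(table3))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper), width = 0.2
    )
  }
  p + ggplot2::labs(x = "ROI configuration", y = "ICC(2,1)",
                    title = "Inter-method agreement per ROI configuration") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Pair means against differences, with the bias (solid) and the 95%
#' limits of agreement (dashed) as horizontal lines.
#'
#' @param ba An `alps_ba` from [bland_altman()].
#' @return A ggplot.
#' @export
plot_bland_altman <- function(ba) {
  df <- tibble(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired indices", y = "Difference (DTI - DWI)",
                  title = sprintf("Bland-Altman: bias %.3f, LOA [%.3f, %.3f]",
                                  ba$bias, ba$loa_lower, ba$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Autoplot a study report
#'
#' @param object An `alps_study`.
#' @param type `"distribution"`, `"icc"` or `"bland_altman"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot alps_study
#' @export
autoplot.alps_study <- function(object, type = c("distribution", "icc",
                                                 "bland_altman"), ...) {
  type <- match.arg(type)
  switch(type,
         distribution = plot_alps_distribution(object$results),
         icc = plot_icc_profile(object$table3),
         bland_altman = plot_bland_altman(object$bland_altman))
}
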