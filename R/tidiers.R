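# broom-style tidiers for the fitted/report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ICC fit
#'
#' @param x An `alps_icc`.
#' @param ... Unused.
#' @return One-row tibble with the estimate, both confidence intervals
#'   and the F test.
#' @method tidy alps_icc
#' @export
tidy.alps_icc <- function(x, ...) {
  tibble(estimate = x$icc, conf.low = x$ci_lower, conf.high = x$ci_upper,
         wald.low = x$wald_lower, wald.high = x$wald_upper,
         statistic = x$f_stat, p.value = x$f_p, category = x$category)
}

#' @rdname tidy.alps_icc
#' @method glance alps_icc
#' @export
glance.alps_icc <- function(x, ...) {
  tibble(icc = x$icc, n = x$n, k = x$k, type = x$type,
         msr = x$msr, msc = x$msc, mse = x$mse, degenerate = x$degenerate)
}

#' Tidy a Bland-Altman analysis
#'
#' @param x An `alps_ba`.
#' @param ... Unused.
#' @return One-row tibble with bias and limits of agreement.
#' @method tidy alps_ba
#' @export
tidy.alps_ba <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_lower = x$loa_lower,
         loa_upper = x$loa_upper, n = x$n)
}

#' Tidy a sample-size computation
#'
#' @param x An `alps_power`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy alps_power
#' @export
tidy.alps_power <- function(x, ...) {
  tibble(n_raw = x$n_raw, n_final = x$n_final,
         effect_size = x$effect_size, alpha = x$alpha, power = x$power,
         inflation = x$inflation)
}

#' Tidy a study report
#'
#' @param x An `alps_study`.
#' @param ... Unused.
#' @return The per-(subject, hemisphere, method, configuration) results
#'   tibble.
#' @method tidy alps_study
#' @export
tidy.alps_study <- function(x, ...) {
  x$results
}

#' @rdname tidy.alps_study
#' @method glance alps_study
#' @export
glance.alps_study <- function(x, ...) {
  means <- tapply(x$results$index, x$results$method, mean)
  tibble(
    n_subjects = x$config$n_subjects,
    n_configs = length(unique(x$results$config)),
    n_dropped = length(unique(x$dropped$config)),
    dti_mean = unname(means[["DTI"]]),
    dwi_mean = unname(means[["DWI"]]),
    intermethod_icc_mean = if (!is.null(x$table3)) mean(x$table3$icc) else NA_real_,
    bias = if (!is.null(x$bland_altman)) x$bland_altman$bias else NA_real_,
    seed = x$config$seed
  )
}
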