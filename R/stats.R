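# Reliability statistics: Lilliefors normality, Wilcoxon signed-rank with
# an exact small-sample null, ICC(2,1) with F test and confidence
# intervals, Bland-Altman agreement, and the paired sample-size formula.

# Lilliefors/Kolmogorov-Smirnov statistic against a normal distribution
# with estimated mean and sd.
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

#' Lilliefors test of normality (Monte Carlo p-value)
#'
#' Kolmogorov-Smirnov statistic against a normal with estimated mean and
#' standard deviation; the p-value comes from a seeded Monte Carlo null
#' (standard-normal samples of the same size), so results are
#' deterministic given the seed. `p = (1 + #{D* >= D}) / (n_rep + 1)`.
#'
#' @param x Numeric sample, `n >= 4`, non-constant.
#' @param n_rep Null replicates (default 10000).
#' @param seed Integer seed for the null simulation.
#' @return An object of class `htest` with the statistic `D` and the
#'   Monte Carlo p-value.
#' @export
lilliefors_test <- function(x, n_rep = 10000L, seed = 171L) {
  x <- as.numeric(x)
  if (length(x) < 4) stopf("need n >= 4")
  if (sd(x) == 0) stopf("constant sample: Lilliefors statistic undefined",
                        class = "alpsroi_degenerate_error")
  d <- lilliefors_statistic(x)
  n <- length(x)
  dnull <- with_seed(seed, {
    vapply(seq_len(n_rep),
           function(i) lilliefors_statistic(rnorm(n)), numeric(1))
  })
  p <- (1 + sum(dnull >= d)) / (n_rep + 1)
  structure(
    list(statistic = c(D = d), p.value = p,
         method = sprintf("Lilliefors normality test (Monte Carlo, %d replicates)", n_rep),
         data.name = deparse(substitute(x)), n = n),
    class = "htest"
  )
}

# Exact null distribution of the doubled signed-rank sum 2W over the 2^m
# equiprobable sign assignments, by subset-sum convolution. Midranks make
# ranks half-integers, hence the doubling.
signed_rank_exact_dist <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (ri in r2) {
    if (ri > 0) {
      shifted <- c(numeric(ri), f[seq_len(total + 1 - ri)])
      f <- f + shifted
    } else {
      f <- f * 2
    }
  }
  f / 2^length(r2)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped (Wilcoxon
#' convention) and ties get midranks. For up to `exact_limit` nonzero
#' differences the p-value comes from the exact null distribution over all
#' sign assignments of the ranked absolute differences (computed by
#' convolution, identical to full enumeration); above it, the normal
#' approximation with tie correction and continuity correction is used.
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b Paired samples; or a vector of differences if `b` is `NULL`.
#' @param exact_limit Largest number of nonzero differences for the exact
#'   null (default 25).
#' @return An object of class `htest` with statistic `W` (sum of positive
#'   ranks), the p-value, and `m`, the number of nonzero differences.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_limit = 25L) {
  d <- if (is.null(b)) as.numeric(a) else {
    if (length(a) != length(b)) stopf("a and b must have equal length")
    as.numeric(a) - as.numeric(b)
  }
  if (any(!is.finite(d))) stopf("differences must be finite")
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    warn("all differences are zero; p = 1")
    return(structure(list(statistic = c(W = 0), p.value = 1,
                          method = "Wilcoxon signed-rank test", m = 0L),
                     class = "htest"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (m <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_exact_dist(r2)
    w2 <- as.integer(round(2 * W))
    ple <- sum(f[seq_len(w2 + 1)])
    pge <- sum(f[(w2 + 1):length(f)])
    p <- min(1, 2 * min(ple, pge))
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    v <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-z))
    method <- "Wilcoxon signed-rank test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(W = W), p.value = p, method = method,
                 m = m),
            class = "htest")
}

# ICC agreement category at the conventional 0.5 / 0.75 / 0.9 thresholds.
icc_category <- function(icc) {
  ifelse(is.na(icc), NA_character_,
         ifelse(icc < 0.5, "poor",
                ifelse(icc < 0.75, "moderate",
                       ifelse(icc < 0.9, "good", "excellent"))))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rating ICC from the
#' two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the F test
#' of zero ICC as `MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of freedom.
#' The primary 95% confidence interval is the F-based McGraw-Wong
#' interval (bounded above by 1); a Wald interval from the large-sample
#' variance of an intraclass correlation is reported alongside and may
#' exceed 1. A consistency-type ICC, `(MSR - MSE) / (MSR + (k-1) MSE)`,
#' is available behind the `type` flag.
#'
#' @param ratings Numeric matrix, subjects in rows, raters/methods in
#'   columns; `n >= 5`, `k >= 2`, no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return Object of class `alps_icc` with elements `icc`, `f_stat`,
#'   `f_p`, `ci_lower`, `ci_upper` (F-based), `wald_lower`, `wald_upper`,
#'   mean squares, `n`, `k`, `category` and `degenerate`.
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95,
                    type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stopf("need n >= 5 subjects and k >= 2 raters")
  if (any(!is.finite(ratings))) stopf("ratings must be complete and finite")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  SST <- sum((ratings - gm)^2)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  degenerate <- MSR < 1e-30 && MSE < 1e-30
  icc <- if (degenerate) NA_real_ else if (type == "agreement") {
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  } else {
    (MSR - MSE) / (MSR + (k - 1) * MSE)
  }
  f_stat <- if (MSE > 0) MSR / MSE else Inf
  f_p <- if (degenerate) NA_real_ else
    pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  alpha <- 1 - conf_level
  if (degenerate || is.na(icc)) {
    ci <- c(NA_real_, NA_real_)
    wald <- c(NA_real_, NA_real_)
  } else if (type == "agreement") {
    # McGraw & Wong (1996) F-based interval for ICC(A,1).
    Fj <- if (MSE > 0) MSC / MSE else Inf
    a_ <- k * icc / (n * (1 - icc))
    b_ <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- if (is.finite(Fj)) {
      ((a_ * Fj + b_)^2) /
        ((a_^2 * Fj^2) / (k - 1) + b_^2 / (n - 1))
    } else {
      n - 1
    }
    F1 <- qf(1 - alpha / 2, n - 1, v)
    F2 <- qf(1 - alpha / 2, v, n - 1)
    denom_lo <- F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR
    denom_hi <- k * MSC + (k * n - k - n) * MSE + n * F2 * MSR
    ci <- c(n * (MSR - F1 * MSE) / denom_lo,
            n * (F2 * MSR - MSE) / denom_hi)
    wald <- icc_wald_ci(icc, n, k, conf_level)
  } else {
    FL <- (MSR / MSE) / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    FU <- (MSR / MSE) * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    wald <- icc_wald_ci(icc, n, k, conf_level)
  }
  structure(
    list(icc = icc, f_stat = f_stat, f_p = f_p,
         ci_lower = ci[1], ci_upper = ci[2], ci_method = "F (McGraw-Wong)",
         wald_lower = wald[1], wald_upper = wald[2],
         msr = MSR, msc = MSC, mse = MSE, n = n, k = k,
         conf_level = conf_level, type = type,
         category = icc_category(icc), degenerate = degenerate),
    class = "alps_icc"
  )
}

# Large-sample (Fisher-type) variance of an intraclass correlation; a
# symmetric Wald interval around the estimate, not truncated at 1.
icc_wald_ci <- function(icc, n, k, conf_level) {
  se <- sqrt(2) * (1 - icc) * abs(1 + (k - 1) * icc) /
    sqrt(k * (k - 1) * max(n - 1, 1))
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(icc - z * se, icc + z * se)
}

#' @export
print.alps_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) %s = %.3f (%s)\n", x$type, x$icc, x$category))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n",
              x$n - 1, (x$n - 1) * (x$k - 1), x$f_stat, x$f_p))
  cat(sprintf("  %d%% CI (F-based) [%.3f, %.3f]; Wald [%.3f, %.3f]\n",
              round(100 * x$conf_level), x$ci_lower, x$ci_upper,
              x$wald_lower, x$wald_upper))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean paired difference `mean(a - b)`; the 95% limits of
#' agreement are `bias +/- 1.96 * SD` with the sample standard deviation
#' (n - 1 denominator) of the differences.
#'
#' @param a,b Paired measurements, `n >= 3`.
#' @return Object of class `alps_ba` with `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`, and the per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stopf("a and b must have equal length")
  if (length(a) < 3) stopf("need n >= 3 pairs")
  d <- as.numeric(a) - as.numeric(b)
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         n = length(d), means = (as.numeric(a) + as.numeric(b)) / 2,
         diffs = d),
    class = "alps_ba"
  )
}

#' @export
print.alps_ba <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f, LOA [%.4f, %.4f]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Paired sample-size computation
#'
#' Normal-approximation formula for a two-sided paired test:
#' `n_raw = ((z_{1-alpha/2} + z_{power}) / effect_size)^2`, then an
#' inflation fraction (to allow for non-normal data and the rank test's
#' efficiency) is added before rounding up. With effect size 0.82,
#' alpha 0.05 and power 0.80 this yields about 11.7 raw and 13 final
#' participants.
#'
#' @param effect_size Standardized paired effect, > 0.
#' @param alpha Two-sided significance level.
#' @param power Target power `1 - beta`.
#' @param inflation Fractional add-on before the ceiling (default 0.10).
#' @return Object of class `alps_power`: list with `n_raw`, `n_final` and
#'   the inputs.
#' @export
paired_sample_size <- function(effect_size, alpha = 0.05, power = 0.80,
                               inflation = 0.10) {
  if (effect_size <= 0) stopf("effect_size must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stopf("alpha and power must lie in (0, 1)")
  }
  n_raw <- ((qnorm(1 - alpha / 2) + qnorm(power)) / effect_size)^2
  n_final <- ceiling(n_raw * (1 + inflation))
  structure(list(n_raw = n_raw, n_final = n_final, effect_size = effect_size,
                 alpha = alpha, power = power, inflation = inflation),
            class = "alps_power")
}

#' @export
print.alps_power <- function(x, ...) {
  cat(sprintf("paired sample size: n_raw = %.2f, +%d%% inflation -> n = %d\n",
              x$n_raw, round(100 * x$inflation), x$n_final))
  invisible(x)
}

#' Simulate two-way ratings with known variance components
#'
#' `x[i, j] = mu + s_i + m_j + e_ij` with independent Gaussian subject,
#' rater and error effects. The population absolute-agreement ICC is
#' `sd_subject^2 / (sd_subject^2 + sd_rater^2 + sd_error^2)`.
#'
#' @param n Subjects. @param k Raters/methods.
#' @param sd_subject,sd_rater,sd_error Component standard deviations.
#' @param mu Grand mean. @param seed Integer seed.
#' @return `n x k` matrix.
#' @export
simulate_icc_ratings <- function(n, k, sd_subject, sd_rater, sd_error,
                                 mu = 0, seed = 1L) {
  with_seed(seed, {
    s <- rnorm(n, sd = sd_subject)
    m <- rnorm(k, sd = sd_rater)
    e <- matrix(rnorm(n * k, sd = sd_error), n, k)
    mu + outer(s, rep(1, k)) + outer(rep(1, n), m) + e
  })
}

#' Percentage of configuration pairs
#'
#' Converts a count of unordered configuration pairs into the percentage
#' of all `choose(n_configs, 2)` pairs, the scale on which the
#' inter-configuration ICC matrix is summarized (with 11 configurations,
#' 2 pairs are 3.64% and 53 pairs 96.36%).
#'
#' @param count Number of pairs.
#' @param n_configs Number of ROI configurations (default 11).
#' @return Percentage.
#' @export
pair_percent <- function(count, n_configs = 11L) {
  100 * count / choose(n_configs, 2)
}
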