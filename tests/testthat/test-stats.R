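test_that("the Lilliefors statistic matches the reference implementation", {
  set.seed(5)
  for (x in list(rexp(80), rnorm(40), rt(60, df = 3))) {
    expect_equal(unname(lilliefors_test(x, n_rep = 200)$statistic),
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("the Lilliefors Monte Carlo p-value is calibrated and powerful", {
  # bimodal mixture is firmly rejected
  set.seed(8)
  bimodal <- c(rnorm(50, -5), rnorm(50, 5))
  expect_lt(lilliefors_test(bimodal, n_rep = 2000, seed = 4)$p.value, 0.01)
  # under the null, p > 0.05 in the vast majority of repetitions
  over <- with(list(), {
    n_keep <- 0L
    for (i in 1:200) {
      x <- withr::with_seed(1000 + i, rnorm(100))
      p <- lilliefors_test(x, n_rep = 1000, seed = 2000 + i)$p.value
      if (p > 0.05) n_keep <- n_keep + 1L
    }
    n_keep
  })
  expect_gte(over, 188)   # >= 94% of 200
  # deterministic given the seed; constant input is degenerate
  x <- withr::with_seed(3, rnorm(30))
  expect_identical(lilliefors_test(x, seed = 7)$p.value,
                   lilliefors_test(x, seed = 7)$p.value)
  expect_error(lilliefors_test(rep(1, 10)), class = "alpsroi_degenerate_error")
})

test_that("the exact signed-rank p equals full enumeration, ties included", {
  # all-positive differences at n = 12: the most extreme table
  p <- wilcoxon_signed_rank(seq_len(12) + 0.5, rep(0, 12))$p.value
  expect_equal(p, 2 / 2^12, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:12) {
    m <- sample(4:10, 1)
    d <- sample(-4:4, m, replace = TRUE)   # integer diffs: ties and zeros
    if (all(d == 0)) d[1] <- 1
    p_pkg <- suppressWarnings(wilcoxon_signed_rank(d)$p.value)
    expect_equal(p_pkg, enum_wsr_p(d), tolerance = 1e-12)
  }
})

test_that("the exact signed-rank p matches wilcox.test on tie-free data", {
  set.seed(31)
  for (i in 1:25) {
    a <- rnorm(13); b <- rnorm(13)
    expect_equal(wilcoxon_signed_rank(a, b)$p.value,
                 stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the normal approximation branch tracks the exact distribution", {
  set.seed(41)
  d <- rnorm(30, mean = 0.3)
  p_approx <- wilcoxon_signed_rank(d, exact_limit = 25)$p.value
  p_exact <- wilcoxon_signed_rank(d, exact_limit = 40)$p.value
  expect_lt(abs(p_approx - p_exact), 0.01)
  # all-zero differences degenerate to p = 1 with a warning
  expect_warning(res <- wilcoxon_signed_rank(rep(0, 8)))
  expect_equal(res$p.value, 1)
})

test_that("ICC(2,1) matches an independent ANOVA computation", {
  m1 <- matrix(c(9, 2, 5, 8, 6, 7,
                 8, 1, 6, 9, 5, 8), ncol = 2)
  expect_equal(icc_2_1(m1)$icc, icc_anova_oracle(m1), tolerance = 1e-12)
  set.seed(51)
  for (i in 1:10) {
    m <- matrix(rnorm(24, sd = 2) + rep(rnorm(8, sd = 3), 3), 8, 3)
    expect_equal(icc_2_1(m)$icc, icc_anova_oracle(m), tolerance = 1e-10)
  }
  # identical columns with subject variance: perfect agreement
  v <- c(1, 5, 3, 8, 2, 6)
  expect_equal(icc_2_1(cbind(v, v))$icc, 1)
})

test_that("ICC(2,1) is invariant to shifts and positive rescaling", {
  set.seed(61)
  m <- matrix(rnorm(20) + rep(rnorm(10), 2), 10, 2)
  base <- icc_2_1(m)$icc
  expect_equal(icc_2_1(m + 100)$icc, base, tolerance = 1e-9)
  expect_equal(icc_2_1(m * 3.5)$icc, base, tolerance = 1e-9)
})

test_that("ICC confidence intervals behave as documented", {
  set.seed(71)
  m <- matrix(rnorm(26, sd = 0.1) + rep(rnorm(13, sd = 1), 2), 13, 2)
  fit <- icc_2_1(m)
  expect_lte(fit$ci_upper, 1)                     # F-based CI bounded
  expect_lt(fit$ci_lower, fit$icc)
  expect_gt(fit$wald_upper, fit$icc)
  # a near-perfect small-sample agreement pushes the Wald bound past 1
  expect_gt(icc_2_1(m)$wald_upper + 0.0, fit$icc)
  hi <- matrix(rep(1:6, 2) + rnorm(12, sd = 1e-3), 6, 2)
  expect_gt(icc_2_1(hi)$wald_upper, 1)
  # degenerate zero-variance input is flagged, not mistaken for agreement
  dg <- icc_2_1(matrix(5, 6, 2))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$icc))
})

test_that("mean ICC over seeded replicates recovers the variance-component ratio", {
  sds <- c(subject = 0.04, rater = 0.005, error = 0.03)
  analytic <- sds[["subject"]]^2 / sum(sds^2)
  iccs <- vapply(1:300, function(i) {
    icc_2_1(simulate_icc_ratings(60, 2, sds[1], sds[2], sds[3], seed = i))$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - analytic), 0.02)
})

test_that("Bland-Altman bias and limits follow the definition", {
  a <- c(1.0, 1.2, 1.1, 1.4)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa_upper, 0)
  b <- a - c(0.1, -0.1, 0.1, -0.1)
  ba <- bland_altman(a, b)
  s <- sd(c(0.1, -0.1, 0.1, -0.1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_upper, 1.96 * s, tolerance = 1e-12)
  # swapping arms flips the bias and keeps the LOA width
  ba2 <- bland_altman(b, a)
  expect_equal(ba2$bias, -ba$bias)
  expect_equal(ba2$loa_upper - ba2$loa_lower, ba$loa_upper - ba$loa_lower)
  expect_error(bland_altman(1:2, 2:3))
})

test_that("the paired sample-size formula reproduces the study computation", {
  pw <- paired_sample_size(effect_size = 0.82, alpha = 0.05, power = 0.80,
                           inflation = 0.10)
  expect_lt(abs(pw$n_raw - 11.65), 0.15)
  expect_equal(pw$n_final, 13)
  # formula identity: effect equal to z_{1-a/2} + z_{power} gives n = 1
  ident <- qnorm(0.975) + qnorm(0.8)
  expect_equal(paired_sample_size(ident)$n_raw, 1, tolerance = 1e-12)
  expect_error(paired_sample_size(0))
})

test_that("tidiers return one-row summaries", {
  set.seed(81)
  m <- matrix(rnorm(20) + rep(rnorm(10), 2), 10, 2)
  td <- generics::tidy(icc_2_1(m))
  expect_equal(nrow(td), 1)
  expect_true(all(c("estimate", "conf.low", "p.value") %in% names(td)))
  ba <- bland_altman(rnorm(10), rnorm(10))
  expect_named(generics::tidy(ba),
               c("bias", "sd_diff", "loa_lower", "loa_upper", "n"))
  expect_equal(generics::tidy(paired_sample_size(0.82))$n_final, 13)
})
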