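# Small phantoms and independent oracles used across the suite.

tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(40L, 20L, 8L), ...)
}

noise_free_spec <- function(...) {
  tiny_spec(subject_cv = 0, noise_sigma = 0, ...)
}

# Uniform isotropic phantom: every region at the same diffusivity.
isotropic_spec <- function(d = 0.8e-3) {
  tiny_spec(
    diffusivity_profile = list(csf = d, wm_principal = d, wm_transverse = d,
                               background = d),
    perivascular_delta = 0, periventricular_delta = 0,
    subject_cv = 0, noise_sigma = 0
  )
}

# Brute-force two-sided Wilcoxon signed-rank p over all 2^m sign
# assignments (midranks for ties), independent of the package's
# convolution implementation.
enum_wsr_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Ws <- as.vector(signs %*% r)
  ple <- mean(Ws <= W + 1e-9)
  pge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(ple, pge))
}

# ICC(2,1) absolute agreement from aov() mean squares: an independent
# ANOVA route to the same quantity.
icc_anova_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(as.vector(row(m))),
                   rater = factor(as.vector(col(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  MSR <- tab[1, "Mean Sq"]; MSC <- tab[2, "Mean Sq"]; MSE <- tab[3, "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}
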