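test_that("log-linear fit inverts noise-free simulation exactly", {
  spec <- tiny_spec()
  f <- build_phantom(spec, 2)
  sch <- scheme_dti()
  v <- simulate_dwi(f, sch$bvals, sch$bvecs, noise_sigma = 0)
  tf <- fit_tensor_loglinear(v)
  rel <- max(abs(tf$tensors - f$tensors)) / max(abs(f$tensors))
  expect_lt(rel, 1e-8)
})

test_that("isotropic voxels fit to equal diagonals and zero off-diagonals", {
  f <- build_phantom(isotropic_spec(1.1e-3), 1)
  sch <- scheme_dti()
  tf <- fit_tensor_loglinear(simulate_dwi(f, sch$bvals, sch$bvecs, noise_sigma = 0))
  tens <- matrix(tf$tensors, ncol = 6)
  expect_true(all(abs(tens[, 1:3] - 1.1e-3) < 1e-10))
  expect_true(all(abs(tens[, 4:6]) < 1e-10))
})

test_that("unattenuated signal fits a zero tensor", {
  sch <- scheme_dti()
  sig <- array(1000, dim = c(2, 2, 2, 65))
  v <- diffusion_volume(sig, sch$bvals, sch$bvecs)
  tf <- fit_tensor_loglinear(v)
  expect_true(all(abs(tf$tensors) < 1e-15))
})

test_that("degenerate gradient schemes are rejected", {
  sig <- array(1000, dim = c(1, 1, 1, 7))
  g <- matrix(rep(c(1, 0, 0), each = 6), ncol = 3)
  v <- diffusion_volume(sig, c(0, rep(1000, 6)), rbind(c(0, 0, 0), g))
  expect_error(fit_tensor_loglinear(v), class = "alpsroi_configuration_error")
})

test_that("directional ADC inverts the monoexponential decay analytically", {
  sch <- scheme_dwi()
  sig <- array(0, dim = c(1, 1, 1, 4))
  sig[1, 1, 1, ] <- c(1000, 1000 * exp(-1), 1000, 1200)
  v <- diffusion_volume(sig, sch$bvals, sch$bvecs)
  adc <- directional_adc(v)
  expect_equal(adc$dx[1, 1, 1], 1.0e-3, tolerance = 1e-12)
  expect_equal(adc$dy[1, 1, 1], 0)              # S = S0 -> zero ADC
  expect_equal(adc$dz[1, 1, 1], 0)              # S > S0 floored at zero
  expect_equal(attr(adc, "n_floored"), 1L)
})

test_that("directional ADC equals the fitted tensor diagonal on axis-aligned phantoms", {
  f <- build_phantom(tiny_spec(subject_cv = 0.05, noise_sigma = 0), 3)
  d64 <- scheme_dti(); d3 <- scheme_dwi()
  tf <- fit_tensor_loglinear(simulate_dwi(f, d64$bvals, d64$bvecs, noise_sigma = 0))
  adc <- directional_adc(simulate_dwi(f, d3$bvals, d3$bvecs, noise_sigma = 0))
  scale <- max(abs(f$tensors))
  expect_lt(max(abs(adc$dx - tf$tensors[, , , 1])) / scale, 1e-8)
  expect_lt(max(abs(adc$dy - tf$tensors[, , , 2])) / scale, 1e-8)
  expect_lt(max(abs(adc$dz - tf$tensors[, , , 3])) / scale, 1e-8)
})

test_that("directional ADC is invariant to a common signal rescaling", {
  f <- build_phantom(tiny_spec(), 1)
  sch <- scheme_dwi()
  v <- simulate_dwi(f, sch$bvals, sch$bvecs, noise_sigma = 0)
  v2 <- v
  v2$signal <- v$signal * 3.7
  a1 <- directional_adc(v)
  a2 <- directional_adc(v2)
  expect_equal(a1$dx, a2$dx, tolerance = 1e-12)
  expect_equal(a1$dy, a2$dy, tolerance = 1e-12)
})

test_that("FA spans its analytic limits and matches the eigenvalue formula", {
  mk_field <- function(diag6) {
    structure(list(tensors = array(rep(diag6, each = 1), dim = c(1, 1, 1, 6)),
                   labels = NULL, voxel_size_mm = 2, subject_scale = NULL),
              class = "tensor_field")
  }
  expect_equal(compute_fa(mk_field(c(1e-3, 1e-3, 1e-3, 0, 0, 0)))$fa[1, 1, 1], 0)
  expect_equal(compute_fa(mk_field(c(1e-3, 0, 0, 0, 0, 0)))$fa[1, 1, 1], 1,
               tolerance = 1e-12)
  # closed-form eigenvalue oracle for a cigar tensor
  lam <- c(1.4, 0.4, 0.4) * 1e-3
  expected <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  fam <- compute_fa(mk_field(c(lam, 0, 0, 0)))
  expect_equal(fam$fa[1, 1, 1], expected, tolerance = 1e-12)
  expect_equal(abs(fam$principal_direction[1, 1, 1, ]), c(1, 0, 0),
               tolerance = 1e-12)
  expect_true(all(fam$rgb >= 0 & fam$rgb <= 1))
})

test_that("recovered diffusivities converge to truth as noise vanishes", {
  spec <- tiny_spec(subject_cv = 0)
  f <- build_phantom(spec, 1)
  proj <- f$labels == region_codes()[["projection"]]
  truth <- spec$diffusivity_profile$wm_transverse + spec$perivascular_delta
  sch <- scheme_dti()
  errs <- vapply(c(0.05, 0.02, 0.005), function(sg) {
    tf <- fit_tensor_loglinear(
      simulate_dwi(f, sch$bvals, sch$bvecs, noise_sigma = sg, seed = 11)
    )
    abs(median(tf$tensors[, , , 1][proj]) - truth)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 2e-5)
})
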