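# Diffusion-weighted signal simulation: monoexponential tensor decay with
# Rician (magnitude-MRI) noise.

#' Diffusion volume container
#'
#' @param signal 4D array (three spatial dimensions plus acquisition
#'   index), non-negative, arbitrary units.
#' @param bvals Numeric vector of b-values in s/mm^2, one per acquisition;
#'   at least one must be 0.
#' @param bvecs Matrix (`n_acq x 3`) of gradient directions in the scanner
#'   frame; rows with nonzero b must have unit norm within 1e-8.
#' @param voxel_size_mm Isotropic voxel edge length.
#' @return Object of class `diffusion_volume`. The axis convention is
#'   fixed: RAS, axial slices are constant-z planes.
#' @export
diffusion_volume <- function(signal, bvals, bvecs, voxel_size_mm = 2) {
  d <- dim(signal)
  if (length(d) != 4L) stopf("signal must be a 4D array")
  if (d[4] != length(bvals) || nrow(bvecs) != length(bvals)) {
    stopf("bvals/bvecs must match the acquisition dimension")
  }
  if (!any(bvals == 0)) stopf("at least one b = 0 acquisition is required")
  nz <- bvals > 0
  if (any(nz)) {
    norms <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-8)) {
      stopf("every nonzero-b direction must have unit norm (within 1e-8)",
            class = "alpsroi_input_error")
    }
  }
  if (any(signal < 0)) stopf("signal must be >= 0")
  structure(
    list(signal = signal, bvals = as.numeric(bvals),
         bvecs = unname(as.matrix(bvecs)), voxel_size_mm = voxel_size_mm,
         axis_convention = "RAS; axial slices are constant-z planes"),
    class = "diffusion_volume"
  )
}

# Design row for one acquisition: S = s0 * exp(-b g' D g) with D packed as
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
bmatrix_rows <- function(bvals, bvecs) {
  g <- bvecs
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
        2 * g[, 2] * g[, 3]) * bvals
}

#' Simulate a diffusion-weighted acquisition
#'
#' Noise-free signal follows the monoexponential tensor model
#' `S = s0 * exp(-b g' D g)`; Rician noise is applied as
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2` independent zero-mean Gaussians
#' of standard deviation `noise_sigma * s0`.
#'
#' @param field A `tensor_field`.
#' @param bvals,bvecs Acquisition scheme (see [scheme_dti()]).
#' @param s0 Baseline signal, must be positive.
#' @param noise_sigma Rician noise scale relative to `s0` (0 disables).
#' @param seed Integer seed; the simulation is reproducible from it.
#' @return A [diffusion_volume()].
#' @export
simulate_dwi <- function(field, bvals, bvecs, s0 = 1000, noise_sigma = 0,
                         seed = 1L) {
  if (!inherits(field, "tensor_field")) stopf("field must be a tensor_field")
  if (s0 <= 0) stopf("s0 must be > 0")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  bvecs <- as.matrix(bvecs)
  nz <- bvals > 0
  if (any(nz)) {
    norms <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-8)) {
      stopf("every nonzero-b direction must have unit norm (within 1e-8)",
            class = "alpsroi_input_error")
    }
  }
  gs <- dim(field$tensors)[1:3]
  tens <- matrix(field$tensors, ncol = 6)
  A <- bmatrix_rows(bvals, bvecs)            # n_acq x 6
  S <- s0 * exp(-tens %*% t(A))              # n_vox x n_acq
  if (noise_sigma > 0) {
    sn <- noise_sigma * s0
    S <- with_seed(seed, {
      n1 <- matrix(rnorm(length(S), sd = sn), nrow = nrow(S))
      n2 <- matrix(rnorm(length(S), sd = sn), nrow = nrow(S))
      sqrt((S + n1)^2 + n2^2)
    })
  }
  diffusion_volume(array(S, dim = c(gs, length(bvals))), bvals, bvecs,
                   voxel_size_mm = field$voxel_size_mm)
}

#' Simulate a study cohort
#'
#' Generates, per subject, a ground-truth tensor field plus one
#' 64-direction (DTI arm) and one 3-orthogonal-direction (DWI arm)
#' acquisition at b = 0 and 1000 s/mm^2 from the same field. Subject k's
#' data depend only on `(spec$seed, k)`, not on `n_subjects`.
#'
#' @param spec A `phantom_spec`.
#' @param n_subjects Number of subjects (the emulated study examined 13
#'   volunteers).
#' @param bvalue Nonzero b-value in s/mm^2.
#' @return Object of class `alps_cohort`: list with `spec` and `subjects`,
#'   each subject holding `field`, `dwi64` and `dwi3`.
#' @export
simulate_cohort <- function(spec, n_subjects = 13L, bvalue = 1000) {
  validate_phantom_spec(spec)
  if (!is_count(n_subjects)) stopf("n_subjects must be >= 1")
  sch64 <- scheme_dti(bvalue)
  sch3 <- scheme_dwi(bvalue)
  subjects <- purrr::map(seq_len(n_subjects), function(k) {
    field <- build_phantom(spec, k)
    list(
      subject = k,
      field = field,
      dwi64 = simulate_dwi(field, sch64$bvals, sch64$bvecs, s0 = spec$s0,
                           noise_sigma = spec$noise_sigma,
                           seed = split_seed(spec$seed, k, 2)),
      dwi3 = simulate_dwi(field, sch3$bvals, sch3$bvecs, s0 = spec$s0,
                          noise_sigma = spec$noise_sigma,
                          seed = split_seed(spec$seed, k, 3))
    )
  })
  structure(list(spec = spec, subjects = subjects), class = "alps_cohort")
}

#' @export
print.diffusion_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<diffusion_volume> %d x %d x %d voxels, %d acquisitions\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  b-values: %s s/mm^2; voxel %.1f mm; %s\n",
              paste(unique(x$bvals), collapse = ", "),
              x$voxel_size_mm, x$axis_convention))
  invisible(x)
}

#' @export
print.alps_cohort <- function(x, ...) {
  cat(sprintf("<alps_cohort> %d subjects, grid %s\n",
              length(x$subjects),
              paste(x$spec$grid_shape, collapse = " x ")))
  invisible(x)
}
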