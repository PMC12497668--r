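# Per-voxel diffusion estimation: log-linear tensor fit (DTI arm),
# directional ADCs (DWI arm), FA and color maps for ROI guidance.

# Fraction of S0 used as the signal floor before taking logs.
SIGNAL_FLOOR_FRACTION <- 1e-6

#' Log-linear least-squares tensor fit
#'
#' Solves `ln(S_i / S0) = -b_i g_i' D g_i` per voxel by ordinary least
#' squares for the six unique tensor elements. `S0` is the mean of the
#' b = 0 acquisitions; signals at or below zero are clamped to
#' `1e-6 * S0` before the log. Voxels with `S0 <= 0` get a zero tensor and
#' are flagged.
#'
#' @param volume A [diffusion_volume()] with at least six nonzero-b
#'   directions spanning the rank-6 design space plus at least one b = 0.
#' @return A `tensor_field` (element order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz);
#'   the attribute `zero_voxels` holds the flagged voxel count and
#'   `labels` is `NULL` (fitted fields carry no ground-truth labels).
#' @export
fit_tensor_loglinear <- function(volume) {
  if (!inherits(volume, "diffusion_volume")) stopf("volume must be a diffusion_volume")
  b0 <- volume$bvals == 0
  nz <- !b0
  if (sum(nz) < 6) stopf("need >= 6 nonzero-b acquisitions",
                         class = "alpsroi_configuration_error")
  B <- -bmatrix_rows(volume$bvals[nz], volume$bvecs[nz, , drop = FALSE])
  qrB <- qr(B)
  if (qrB$rank < 6) {
    stopf("gradient scheme is rank-deficient for a tensor fit",
          class = "alpsroi_configuration_error")
  }
  gs <- dim(volume$signal)[1:3]
  nvox <- prod(gs)
  S <- matrix(volume$signal, nrow = nvox)
  s0 <- rowMeans(S[, b0, drop = FALSE])
  zero_vox <- s0 <= 0
  s0safe <- ifelse(zero_vox, 1, s0)
  Y <- log(pmax(S[, nz, drop = FALSE], SIGNAL_FLOOR_FRACTION * s0safe) / s0safe)
  theta <- t(qr.coef(qrB, t(Y)))             # n_vox x 6
  theta[zero_vox, ] <- 0
  structure(
    list(tensors = array(theta, dim = c(gs, 6L)), labels = NULL,
         voxel_size_mm = volume$voxel_size_mm, subject_scale = NULL),
    class = "tensor_field",
    zero_voxels = sum(zero_vox)
  )
}

#' Directional apparent diffusivities from a 3-direction acquisition
#'
#' Computes `d_axis = -ln(S_axis / S0) / b` per voxel for the readout (x),
#' phase (y) and slice (z) axes, exactly as the DWI-ALPS method reads
#' diffusivities directly from the scan. Signals are clamped to
#' `1e-6 * S0` before the log; negative estimates are floored at 0 and
#' counted.
#'
#' @param volume A [diffusion_volume()] whose nonzero-b acquisitions
#'   include the three scanner axes.
#' @return Object of class `adc_map`: list with 3D arrays `dx`, `dy`, `dz`
#'   (mm^2/s) and `voxel_size_mm`; attribute `n_floored` counts negative
#'   estimates set to zero.
#' @export
directional_adc <- function(volume) {
  if (!inherits(volume, "diffusion_volume")) stopf("volume must be a diffusion_volume")
  b0 <- volume$bvals == 0
  gs <- dim(volume$signal)[1:3]
  nvox <- prod(gs)
  S <- matrix(volume$signal, nrow = nvox)
  s0 <- rowMeans(S[, b0, drop = FALSE])
  s0safe <- ifelse(s0 <= 0, 1, s0)
  axes <- dwi_directions()
  out <- list()
  n_floored <- 0L
  for (i in 1:3) {
    j <- which(volume$bvals > 0 &
                 abs(abs(volume$bvecs %*% axes[i, ]) - 1) < 1e-6)
    if (length(j) < 1) {
      stopf("missing acquisition along the %s axis", c("x", "y", "z")[i],
            class = "alpsroi_input_error")
    }
    j <- j[1]
    d <- -log(pmax(S[, j], SIGNAL_FLOOR_FRACTION * s0safe) / s0safe) /
      volume$bvals[j]
    n_floored <- n_floored + sum(d < 0)
    d[d < 0] <- 0
    out[[c("dx", "dy", "dz")[i]]] <- array(d, dim = gs)
  }
  structure(c(out, list(voxel_size_mm = volume$voxel_size_mm)),
            class = "adc_map", n_floored = n_floored)
}

#' Fractional anisotropy and principal-direction maps
#'
#' FA is the normalized eigenvalue dispersion
#' `sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`; negative
#' eigenvalues are clipped to zero first. The RGB composite is
#' `(|v_x|, |v_y|, |v_z|) * FA` from the principal eigenvector, the
#' standard color-coded FA map used to identify the projection (blue, z)
#' and association (green, y) areas.
#'
#' @param field A `tensor_field`.
#' @return Object of class `fa_map`: list with `fa` (3D, in `[0, 1]`),
#'   `principal_direction` (`[nx, ny, nz, 3]` unit vectors) and `rgb`
#'   (`[nx, ny, nz, 3]` in `[0, 1]`).
#' @export
compute_fa <- function(field) {
  if (!inherits(field, "tensor_field")) stopf("field must be a tensor_field")
  gs <- dim(field$tensors)[1:3]
  tens <- matrix(field$tensors, ncol = 6)
  nvox <- nrow(tens)
  fa <- numeric(nvox)
  pd <- matrix(0, nvox, 3)
  nonzero <- rowSums(abs(tens)) > 0
  for (i in which(nonzero)) {
    e <- eigen(tensor_matrix(tens[i, ]), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    nrm <- sqrt(sum(lam^2))
    if (nrm > 0) {
      fa[i] <- min(1, sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / nrm)
    }
    pd[i, ] <- e$vectors[, which.max(lam)]
  }
  rgb <- abs(pd) * fa
  structure(
    list(fa = array(fa, dim = gs),
         principal_direction = array(pd, dim = c(gs, 3L)),
         rgb = array(pmin(1, pmax(0, rgb)), dim = c(gs, 3L))),
    class = "fa_map"
  )
}

#' Color composite from directional ADCs
#'
#' The DWI-arm analogue of the color-coded FA map: red, green and blue
#' channels carry the diffusivities along x, y and z, normalized by the
#' global maximum across the three maps.
#'
#' @param adc An `adc_map`.
#' @return `[nx, ny, nz, 3]` array with channels in `[0, 1]`.
#' @export
compute_dwi_rgb <- function(adc) {
  if (!inherits(adc, "adc_map")) stopf("adc must be an adc_map")
  mx <- max(adc$dx, adc$dy, adc$dz, 1e-30)
  gs <- dim(adc$dx)
  array(c(adc$dx, adc$dy, adc$dz) / mx, dim = c(gs, 3L))
}
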