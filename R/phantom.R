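# Synthetic periventricular phantom: ground-truth tensor fields emulating
# the anatomy interrogated by the ALPS method.

# Diffusivity of free water at body temperature; hard ceiling for any
# configured diffusivity (mm^2/s).
FREE_WATER_CEILING <- 3.5e-3

# Integer label codes used in label maps.
REGION_CODES <- c(
  background      = 0L,
  ventricle       = 1L,
  projection      = 2L,
  association     = 3L,
  subcortical     = 4L,
  periventricular = 5L
)

#' Region label codes
#'
#' Integer codes used in phantom label maps. `periventricular` marks the
#' one-voxel margin hugging the lateral ventricle, where the paravenous
#' interstitial-fluid component along x is strongest.
#'
#' @return Named integer vector.
#' @export
region_codes <- function() REGION_CODES

#' Default phantom region geometry
#'
#' Axis-aligned boxes (1-based, inclusive voxel indices) for the lateral
#' ventricle, projection area (superior corona radiata, fibers head-foot),
#' association area (superior longitudinal fasciculus, fibers
#' anterior-posterior) and subcortical band (fibers left-right), mirrored
#' across the midline. The x axis is left-right, y anterior-posterior,
#' z inferior-superior (RAS); axial slices are constant-z planes.
#'
#' @param grid_shape Integer vector of voxels per axis `c(nx, ny, nz)`;
#'   `nx` must be even and at least 40 so both hemispheres fit.
#' @return Tibble with columns `region`, `hemisphere`, `x0`, `x1`, `y0`,
#'   `y1`, `z0`, `z1`.
#' @export
default_region_geometry <- function(grid_shape = c(40L, 40L, 24L)) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  if (nx %% 2 != 0 || nx < 40) {
    stopf("grid_shape[1] must be even and >= 40 (got %d)", nx,
          class = "alpsroi_geometry_error")
  }
  mid <- nx %/% 2
  y0 <- max(2L, as.integer(round(0.25 * ny)))
  y1 <- min(ny - 1L, as.integer(round(0.75 * ny)))
  z0 <- max(2L, as.integer(round(0.30 * nz)))
  z1 <- min(nz - 1L, as.integer(round(0.70 * nz)))
  if (y1 - y0 < 4L || z1 < z0) {
    stopf("grid too small along y or z for the default geometry",
          class = "alpsroi_geometry_error")
  }
  # Right-hemisphere x extents, medial to lateral; left is the mirror
  # x -> nx + 1 - x. One background/periventricular voxel separates the
  # ventricle from the projection area and the projection from the
  # association area, so legal ROI placements exist.
  right <- tibble(
    region = c("ventricle", "projection", "association", "subcortical"),
    x0 = mid + c(1L, 6L, 11L, 16L),
    x1 = mid + c(4L, 9L, 14L, 18L)
  )
  left <- tibble(
    region = right$region,
    x0 = nx + 1L - right$x1,
    x1 = nx + 1L - right$x0
  )
  geom <- dplyr::bind_rows(
    dplyr::mutate(right, hemisphere = "right"),
    dplyr::mutate(left, hemisphere = "left")
  )
  dplyr::select(
    dplyr::mutate(geom, y0 = y0, y1 = y1, z0 = z0, z1 = z1),
    "region", "hemisphere", "x0", "x1", "y0", "y1", "z0", "z1"
  )
}

#' Phantom specification
#'
#' Defines the ground-truth periventricular tensor field and the noise and
#' between-subject variability of the simulated cohort.
#'
#' @param grid_shape Voxels per axis, `c(nx, ny, nz)`.
#' @param voxel_size_mm Isotropic voxel edge length in mm (acquisitions in
#'   the emulated study use 2 mm).
#' @param diffusivity_profile Named list with elements `csf` (isotropic
#'   ventricle diffusivity), `wm_principal` and `wm_transverse` (white
#'   matter eigenvalues along/across the fiber axis) and `background`
#'   (isotropic), all in mm^2/s.
#' @param perivascular_delta Increment added to the left-right diagonal
#'   element Dxx in the projection and association areas (mm^2/s): the
#'   ground-truth perivascular ("glymphatic") diffusion component the ALPS
#'   index targets.
#' @param periventricular_delta Increment added to Dxx in the one-voxel
#'   margin around the ventricle, where the paravenous fluid runs
#'   left-right along the periventricular veins. ROIs placed too close to
#'   the ventricle pick up this component and inflate the index.
#' @param subject_cv Coefficient of variation of the per-subject log-normal
#'   scalings (one applied to all diffusivities, one to the perivascular
#'   deltas).
#' @param noise_sigma Rician noise scale relative to the b = 0 signal.
#' @param s0 Baseline (b = 0) signal amplitude, arbitrary units.
#' @param seed Integer master seed for subject scalings and noise.
#' @param region_geometry Optional custom geometry as returned by
#'   [default_region_geometry()].
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 24L),
                         voxel_size_mm = 2,
                         diffusivity_profile = list(
                           csf = 3.0e-3,
                           wm_principal = 1.4e-3,
                           wm_transverse = 0.4e-3,
                           background = 0.8e-3
                         ),
                         perivascular_delta = 0.3e-3,
                         periventricular_delta = 1.2e-3,
                         subject_cv = 0.05,
                         noise_sigma = 0.02,
                         s0 = 1000,
                         seed = 20250411L,
                         region_geometry = NULL) {
  grid_shape <- as.integer(grid_shape)
  spec <- structure(
    list(
      grid_shape = grid_shape,
      voxel_size_mm = voxel_size_mm,
      diffusivity_profile = diffusivity_profile,
      perivascular_delta = perivascular_delta,
      periventricular_delta = periventricular_delta,
      subject_cv = subject_cv,
      noise_sigma = noise_sigma,
      s0 = s0,
      seed = as.integer(seed),
      region_geometry = region_geometry %||% default_region_geometry(grid_shape)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks that all diffusivities (including the perivascular increments)
#' lie in `[0, 3.5e-3]` mm^2/s, that region boxes are pairwise disjoint and
#' inside the grid, and that the projection and association boxes are
#' separated from the ventricle and from each other by at least one voxel
#' along x, so that legal ROI placements exist.
#'
#' @param spec A `phantom_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_phantom_spec <- function(spec) {
  prof <- spec$diffusivity_profile
  needed <- c("csf", "wm_principal", "wm_transverse", "background")
  if (!all(needed %in% names(prof))) {
    stopf("diffusivity_profile must contain %s", paste(needed, collapse = ", "))
  }
  dvals <- c(
    unlist(prof[needed]),
    prof$wm_transverse + spec$perivascular_delta,
    prof$wm_transverse + spec$periventricular_delta
  )
  if (any(!is.finite(dvals)) || any(dvals < 0)) {
    stopf("diffusivities must be finite and non-negative",
          class = "alpsroi_parameter_error")
  }
  if (any(dvals > FREE_WATER_CEILING)) {
    stopf("a diffusivity (base + delta) exceeds the free-water ceiling %.1e mm^2/s",
          FREE_WATER_CEILING, class = "alpsroi_parameter_error")
  }
  if (spec$subject_cv < 0 || spec$noise_sigma < 0 || spec$s0 <= 0) {
    stopf("subject_cv and noise_sigma must be >= 0 and s0 > 0",
          class = "alpsroi_parameter_error")
  }
  geom <- spec$region_geometry
  gs <- spec$grid_shape
  if (any(geom$x0 < 1 | geom$y0 < 1 | geom$z0 < 1 |
          geom$x1 > gs[1] | geom$y1 > gs[2] | geom$z1 > gs[3] |
          geom$x0 > geom$x1 | geom$y0 > geom$y1 | geom$z0 > geom$z1)) {
    stopf("region boxes must be non-empty and inside the grid",
          class = "alpsroi_geometry_error")
  }
  n <- nrow(geom)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- geom[i, ]; b <- geom[j, ]
      overlap <- a$x0 <= b$x1 && b$x0 <= a$x1 &&
        a$y0 <= b$y1 && b$y0 <= a$y1 &&
        a$z0 <= b$z1 && b$z0 <= a$z1
      if (overlap) {
        stopf("region boxes overlap: %s/%s and %s/%s",
              a$region, a$hemisphere, b$region, b$hemisphere,
              class = "alpsroi_geometry_error")
      }
    }
  }
  # >= 1 empty voxel along x between ventricle/projection and
  # projection/association within each hemisphere.
  for (h in unique(geom$hemisphere)) {
    gh <- geom[geom$hemisphere == h, ]
    box <- function(r) gh[gh$region == r, ]
    xgap <- function(a, b) max(b$x0 - a$x1, a$x0 - b$x1) - 1L
    pairs <- list(c("ventricle", "projection"),
                  c("ventricle", "association"),
                  c("projection", "association"))
    for (p in pairs) {
      if (xgap(box(p[1]), box(p[2])) < 1L) {
        stopf("%s and %s boxes (%s) must be separated by >= 1 voxel along x",
              p[1], p[2], h, class = "alpsroi_geometry_error")
      }
    }
  }
  invisible(spec)
}

#' Build the phantom label map
#'
#' @param spec A `phantom_spec`.
#' @return Integer 3D array with codes from [region_codes()]. The
#'   periventricular band is the in-plane one-voxel dilation of the
#'   ventricle boxes, excluding every other region.
#' @export
build_labels <- function(spec) {
  gs <- spec$grid_shape
  lab <- array(REGION_CODES[["background"]], dim = gs)
  geom <- spec$region_geometry
  for (i in seq_len(nrow(geom))) {
    g <- geom[i, ]
    lab[g$x0:g$x1, g$y0:g$y1, g$z0:g$z1] <- REGION_CODES[[g$region]]
  }
  vent <- geom[geom$region == "ventricle", ]
  for (i in seq_len(nrow(vent))) {
    g <- vent[i, ]
    xs <- max(1L, g$x0 - 1L):min(gs[1], g$x1 + 1L)
    ys <- max(1L, g$y0 - 1L):min(gs[2], g$y1 + 1L)
    zs <- g$z0:g$z1
    band <- lab[xs, ys, zs, drop = FALSE]
    band[band == REGION_CODES[["background"]]] <- REGION_CODES[["periventricular"]]
    lab[xs, ys, zs] <- band
  }
  lab
}

# Per-subject log-normal scalings: unit mean, coefficient of variation cv.
# Element "tissue" multiplies every diffusivity (cancels in the ALPS
# ratio); "delta" multiplies the perivascular increments (moves the true
# index, making between-subject variance in the index non-degenerate).
subject_scales <- function(spec, subject_index) {
  if (spec$subject_cv <= 0) {
    return(c(tissue = 1, delta = 1))
  }
  sdlog <- sqrt(log1p(spec$subject_cv^2))
  with_seed(split_seed(spec$seed, subject_index), {
    z <- rnorm(2)
    c(tissue = exp(z[1] * sdlog - sdlog^2 / 2),
      delta  = exp(z[2] * sdlog - sdlog^2 / 2))
  })
}

#' Build a ground-truth tensor field
#'
#' Constructs the per-voxel diffusion tensor field for one subject.
#' Ventricle voxels are isotropic at the CSF diffusivity; projection voxels
#' have their largest eigenvalue along z, association along y, subcortical
#' along x; the perivascular delta is added to Dxx in the projection and
#' association areas and the (stronger) periventricular delta to Dxx in the
#' band hugging the ventricle. Two deterministic per-subject log-normal
#' scalings (seeded from `spec$seed` and `subject_index`) multiply all
#' diffusivities and the deltas respectively.
#'
#' @param spec A `phantom_spec`.
#' @param subject_index Positive integer identifying the subject.
#' @return Object of class `tensor_field`: list with `tensors` (4D array
#'   `[nx, ny, nz, 6]`, element order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, in
#'   mm^2/s), `labels` (integer array), `voxel_size_mm` and
#'   `subject_scale`.
#' @export
build_phantom <- function(spec, subject_index = 1L) {
  validate_phantom_spec(spec)
  if (!is_count(subject_index)) stopf("subject_index must be a positive integer")
  prof <- spec$diffusivity_profile
  lab <- build_labels(spec)
  sc <- subject_scales(spec, subject_index)

  gs <- spec$grid_shape
  nvox <- prod(gs)
  tens <- matrix(0, nrow = nvox, ncol = 6)
  labv <- as.vector(lab)
  tr <- prof$wm_transverse
  pr <- prof$wm_principal
  d_pv <- spec$perivascular_delta * sc[["delta"]]
  d_band <- spec$periventricular_delta * sc[["delta"]]

  # (Dxx, Dyy, Dzz) per region; fibers: projection z, association y,
  # subcortical x.
  diag3 <- list(
    background      = rep(prof$background, 3),
    ventricle       = rep(prof$csf, 3),
    projection      = c(tr + d_pv, tr, pr),
    association     = c(tr + d_pv, pr, tr),
    subcortical     = c(pr, tr, tr),
    periventricular = c(tr + d_band, tr, tr)
  )
  for (region in names(diag3)) {
    idx <- labv == REGION_CODES[[region]]
    if (any(idx)) {
      tens[idx, 1:3] <- matrix(diag3[[region]], nrow = sum(idx), ncol = 3,
                               byrow = TRUE)
    }
  }
  tens <- tens * sc[["tissue"]]
  structure(
    list(
      tensors = array(tens, dim = c(gs, 6L)),
      labels = lab,
      voxel_size_mm = spec$voxel_size_mm,
      subject_scale = sc
    ),
    class = "tensor_field"
  )
}

#' Validate a tensor field
#'
#' Checks symmetry representation (6 unique elements) and positive
#' semi-definiteness: non-negative diagonal and non-negative eigenvalues
#' (within `tol`).
#'
#' @param field A `tensor_field`.
#' @param tol Eigenvalue tolerance.
#' @return `field`, invisibly; errors on violation.
#' @export
validate_tensor_field <- function(field, tol = 1e-12) {
  d <- dim(field$tensors)
  if (length(d) != 4L || d[4] != 6L) stopf("tensors must be [nx, ny, nz, 6]")
  tens <- matrix(field$tensors, ncol = 6)
  if (any(!is.finite(tens))) stopf("tensors must be finite")
  if (any(tens[, 1:3] < -tol)) stopf("diagonal elements must be >= 0")
  uniq <- unique(round(tens, 12))
  for (i in seq_len(nrow(uniq))) {
    ev <- eigen(tensor_matrix(uniq[i, ]), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(abs(ev), 1e-30)) {
      stopf("tensor field contains a non-positive-semi-definite tensor")
    }
  }
  invisible(field)
}

# 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) -> symmetric 3x3 matrix.
tensor_matrix <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), nrow = 3)
}

#' Analytic ground-truth ALPS index of a phantom
#'
#' For the population phantom (unit subject scaling) the ROI-mean
#' diffusivities are exact region values, so the index has the closed form
#' `(2 * (transverse + delta)) / (2 * transverse) = 1 + delta / transverse`.
#'
#' @param spec A `phantom_spec`.
#' @param subject_index Optional subject; if supplied, the subject's delta
#'   scaling is applied.
#' @return The true ALPS index (dimensionless).
#' @export
alps_ground_truth <- function(spec, subject_index = NULL) {
  sc <- if (is.null(subject_index)) 1 else
    subject_scales(spec, subject_index)[["delta"]]
  tr <- spec$diffusivity_profile$wm_transverse
  1 + spec$perivascular_delta * sc / tr
}

#' @export
print.phantom_spec <- function(x, ...) {
  gs <- x$grid_shape
  cat(sprintf("<phantom_spec> %d x %d x %d voxels @ %.1f mm\n",
              gs[1], gs[2], gs[3], x$voxel_size_mm))
  cat(sprintf("  perivascular delta %.2e, periventricular delta %.2e mm^2/s\n",
              x$perivascular_delta, x$periventricular_delta))
  cat(sprintf("  subject CV %.3f, noise sigma %.3f, seed %d\n",
              x$subject_cv, x$noise_sigma, x$seed))
  cat(sprintf("  true ALPS index %.4f\n", alps_ground_truth(x)))
  invisible(x)
}
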