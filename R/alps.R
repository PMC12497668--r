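# ALPS index computation per subject, hemisphere, method and ROI
# configuration.

#' ALPS index
#'
#' `mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)`, evaluated as the
#' algebraically identical two-term-sum ratio
#' `(dx_proj + dx_assoc) / (dy_proj + dz_assoc)` to avoid double rounding.
#' The index is dimensionless and invariant to a common positive rescaling
#' of all four inputs.
#'
#' @param dx_proj,dx_assoc Left-right diffusivities in the projection and
#'   association ROIs (mm^2/s).
#' @param dy_proj Anterior-posterior diffusivity in the projection ROI.
#' @param dz_assoc Inferior-superior diffusivity in the association ROI.
#' @return The ALPS ratio. Vectorized over its arguments.
#' @export
alps_index <- function(dx_proj, dx_assoc, dy_proj, dz_assoc) {
  vals <- cbind(dx_proj, dx_assoc, dy_proj, dz_assoc)
  if (any(!is.finite(vals))) stopf("ALPS inputs must be finite")
  denom <- dy_proj + dz_assoc
  if (any(denom <= 0)) {
    stopf("mean(dy_proj, dz_assoc) must be > 0",
          class = "alpsroi_computation_error")
  }
  (dx_proj + dx_assoc) / denom
}

# Diffusivity maps used by each method: the fitted tensor diagonal for
# DTI, the directly measured axis ADCs for DWI; the formula is the same.
alps_maps <- function(x, method) {
  if (method == "DTI") {
    if (!inherits(x, "tensor_field")) stopf("DTI requires a tensor_field")
    list(dx = x$tensors[, , , 1], dy = x$tensors[, , , 2],
         dz = x$tensors[, , , 3])
  } else {
    if (!inherits(x, "adc_map")) stopf("DWI requires an adc_map")
    list(dx = x$dx, dy = x$dy, dz = x$dz)
  }
}

#' ALPS indices for one subject
#'
#' Extracts the ROI-mean diffusivities and computes one index per
#' (hemisphere, configuration). The DTI method reads Dxx from the
#' projection and association ROIs, Dyy from the projection ROI and Dzz
#' from the association ROI of the fitted tensor; the DWI method
#' substitutes the directly measured dx, dy, dz maps.
#'
#' @param x A `tensor_field` (method `"DTI"`) or `adc_map` (`"DWI"`).
#' @param placements Tibble from [place_study_rois()].
#' @param method `"DTI"` or `"DWI"`.
#' @param subject_id Identifier stored in the result.
#' @return Tibble with columns `subject`, `hemisphere`, `method`,
#'   `config`, the four ROI-mean diffusivities and `index`.
#' @export
subject_alps <- function(x, placements, method = c("DTI", "DWI"),
                         subject_id = 1L) {
  method <- match.arg(method)
  maps <- alps_maps(x, method)
  wide <- tidyr::pivot_wider(placements, names_from = "area",
                             values_from = "placement")
  purrr::pmap_dfr(wide, function(hemisphere, config, projection, association) {
    dx_proj <- extract_mean(maps$dx, projection)
    dx_assoc <- extract_mean(maps$dx, association)
    dy_proj <- extract_mean(maps$dy, projection)
    dz_assoc <- extract_mean(maps$dz, association)
    tibble(subject = subject_id, hemisphere = hemisphere, method = method,
           config = config, dx_proj = dx_proj, dx_assoc = dx_assoc,
           dy_proj = dy_proj, dz_assoc = dz_assoc,
           index = alps_index(dx_proj, dx_assoc, dy_proj, dz_assoc))
  })
}

#' Average the two hemispheric indices
#'
#' Arithmetic mean of the left and right index per (subject, method,
#' configuration). Hemisphere averaging is a derived, opt-in quantity:
#' hemispheres should also be reported separately, since disease can be
#' lateralized.
#'
#' @param results Tibble from [subject_alps()] (possibly row-bound over
#'   subjects and methods).
#' @return Tibble with `subject`, `method`, `config`, `index` and
#'   `hemisphere = "avg"`.
#' @export
hemisphere_average <- function(results) {
  counts <- dplyr::count(results, .data$subject, .data$method, .data$config)
  if (any(counts$n != 2)) {
    stopf("each (subject, method, config) needs both hemispheres",
          class = "alpsroi_input_error")
  }
  dplyr::summarise(
    dplyr::group_by(results, .data$subject, .data$method, .data$config),
    index = mean(.data$index), .groups = "drop"
  ) |>
    dplyr::mutate(hemisphere = "avg") |>
    dplyr::select("subject", "hemisphere", "method", "config", "index")
}
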