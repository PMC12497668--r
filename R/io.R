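# File interfaces: NIfTI volumes (via RNifti), FSL-dialect bval/bvec text
# files, label maps, placement records (JSON) and phantom specs (YAML).

#' Read / write FSL-style b-value and b-vector files
#'
#' `bval`: a single line of space-separated b-values. `bvec`: three lines
#' holding the x, y and z components of every direction.
#'
#' @param bvals Numeric vector. @param bvecs `n x 3` matrix.
#' @param path File path.
#' @return The written path (writers, invisibly); numeric vector / matrix
#'   (readers).
#' @export
write_bvals <- function(bvals, path) {
  writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname write_bvals
#' @export
write_bvecs <- function(bvecs, path) {
  bvecs <- as.matrix(bvecs)
  lines <- apply(t(bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bvals
#' @export
read_bvals <- function(path) {
  as.numeric(strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]])
}

#' @rdname write_bvals
#' @export
read_bvecs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3) stopf("bvec file must have three lines")
  comp <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(unique(lengths(comp))) != 1) stopf("ragged bvec file")
  cbind(x = comp[[1]], y = comp[[2]], z = comp[[3]])
}

# Attach isotropic voxel dimensions to an array and write it as NIfTI.
write_nifti_array <- function(arr, path, voxel_size_mm) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(rep(voxel_size_mm, 3), rep(1, nd - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a diffusion volume as NIfTI plus bval/bvec
#'
#' @param volume A [diffusion_volume()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval` and `<prefix>.bvec`.
#' @return Invisible character vector of the three paths.
#' @export
write_diffusion_volume <- function(volume, prefix) {
  nii <- paste0(prefix, ".nii.gz")
  write_nifti_array(volume$signal, nii, volume$voxel_size_mm)
  write_bvals(volume$bvals, paste0(prefix, ".bval"))
  write_bvecs(volume$bvecs, paste0(prefix, ".bvec"))
  invisible(c(nii, paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}

#' Read a diffusion volume from NIfTI plus bval/bvec
#'
#' Entry point for real acquisitions: a 4D NIfTI with FSL-style bval/bvec
#' text files.
#'
#' @param nifti_path 4D NIfTI file.
#' @param bval_path,bvec_path FSL-dialect text files.
#' @return A [diffusion_volume()].
#' @export
read_diffusion_volume <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  diffusion_volume(arr, read_bvals(bval_path), read_bvecs(bvec_path),
                   voxel_size_mm = pd[1])
}

#' Write / read an integer label map as NIfTI
#'
#' @param labels Integer 3D array (codes from [region_codes()]).
#' @param path NIfTI path. @param voxel_size_mm Voxel edge length.
#' @return Path (writer, invisibly) or integer array (reader).
#' @export
write_label_map <- function(labels, path, voxel_size_mm = 2) {
  write_nifti_array(labels, path, voxel_size_mm)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  storage.mode(arr) <- "integer"
  arr
}

#' Write a fitted tensor field as a 6-volume NIfTI
#'
#' Element order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz along the fourth dimension.
#'
#' @param field A `tensor_field`. @param path NIfTI path.
#' @return Path, invisibly.
#' @export
write_tensor_field <- function(field, path) {
  write_nifti_array(field$tensors, path, field$voxel_size_mm)
}

#' Serialize / restore ROI placements as JSON
#'
#' @param placements Tibble from [place_study_rois()].
#' @param path JSON path.
#' @return Path (writer, invisibly) or placements tibble (reader).
#' @export
placements_to_json <- function(placements, path) {
  recs <- purrr::pmap(placements, function(hemisphere, area, config, placement) {
    list(config = config, hemisphere = hemisphere, area = area,
         anchor = as.integer(placement$anchor))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname placements_to_json
#' @export
placements_from_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(recs, function(r) {
    tibble(hemisphere = r$hemisphere, area = r$area, config = r$config,
           placement = list(roi_placement(r$config,
                                          unlist(r$anchor, use.names = FALSE),
                                          r$hemisphere, r$area)))
  })
}

#' Serialize / restore a phantom spec as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML path.
#' @return Path (writer, invisibly) or `phantom_spec` (reader).
#' @export
phantom_spec_to_yaml <- function(spec, path) {
  obj <- unclass(spec)
  obj$region_geometry <- as.data.frame(obj$region_geometry)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname phantom_spec_to_yaml
#' @export
phantom_spec_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  geom <- as_tibble(as.data.frame(lapply(obj$region_geometry, unlist)))
  phantom_spec(
    grid_shape = unlist(obj$grid_shape),
    voxel_size_mm = obj$voxel_size_mm,
    diffusivity_profile = obj$diffusivity_profile,
    perivascular_delta = obj$perivascular_delta,
    periventricular_delta = obj$periventricular_delta,
    subject_cv = obj$subject_cv,
    noise_sigma = obj$noise_sigma,
    s0 = obj$s0,
    seed = obj$seed,
    region_geometry = geom
  )
}
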