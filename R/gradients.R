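# Gradient direction sets for the two simulated acquisitions.

#' Well-spread 64-direction gradient set
#'
#' Deterministic closed-form direction table: points of a Fibonacci
#' (golden-angle) spiral on the upper hemisphere. The set is well spread,
#' spans the rank-6 tensor design space, and stands in for the vendor
#' 64-direction scheme of the emulated DTI acquisition.
#'
#' @param n Number of directions (default 64).
#' @return `n x 3` matrix of unit row vectors (x = left-right/readout,
#'   y = anterior-posterior/phase, z = inferior-superior/slice).
#' @export
alps_directions_64 <- function(n = 64L) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Three orthogonal scanner-axis directions
#'
#' The DWI arm measures diffusivity directly along the readout (x),
#' phase-encoding (y) and slice-encoding (z) axes.
#'
#' @return `3 x 3` identity-row matrix.
#' @export
dwi_directions <- function() {
  d <- diag(3)
  dimnames(d) <- list(NULL, c("x", "y", "z"))
  d
}

#' Acquisition scheme for the 64-direction DTI arm
#'
#' One b = 0 acquisition followed by 64 diffusion-weighted directions at
#' the given b-value.
#'
#' @param bvalue Diffusion weighting in s/mm^2 (default 1000).
#' @return List with `bvals` (length 65) and `bvecs` (65 x 3).
#' @export
scheme_dti <- function(bvalue = 1000) {
  dirs <- alps_directions_64()
  list(bvals = c(0, rep(bvalue, nrow(dirs))),
       bvecs = rbind(c(0, 0, 0), dirs))
}

#' Acquisition scheme for the 3-direction DWI arm
#'
#' @param bvalue Diffusion weighting in s/mm^2 (default 1000).
#' @return List with `bvals` (length 4) and `bvecs` (4 x 3).
#' @export
scheme_dwi <- function(bvalue = 1000) {
  list(bvals = c(0, rep(bvalue, 3)),
       bvecs = rbind(c(0, 0, 0), dwi_directions()))
}
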