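#' Subtract a blank (reference) phase map
#'
#' Removes the system background aberration measured on a sample-free
#' acquisition: pixelwise difference of the two unwrapped maps, re-anchored
#' to zero-median over the background mask.
#'
#' @param phase \code{unwrapped_phase} of the sample acquisition
#' @param blank \code{unwrapped_phase} of the blank acquisition (or a bare
#'   matrix)
#' @param background anchor mask as in \code{\link{unwrap_phase}}
#' @return an \code{unwrapped_phase}
#' @export
reference_subtract <- function(phase, blank, background = NULL) {
  p <- if (inherits(phase, "unwrapped_phase")) phase$phase else phase
  b <- if (inherits(blank, "unwrapped_phase")) blank$phase else blank
  if (!all(dim(p) == dim(b))) stop("phase and blank shapes differ")
  out <- p - b
  d <- dim(out)
  if (is.null(background)) {
    bg <- matrix(FALSE, d[1], d[2])
    bg[c(1:2, d[1] - 1, d[1]), ] <- TRUE
    bg[, c(1:2, d[2] - 1, d[2])] <- TRUE
    background <- bg
  }
  out <- out - stats::median(out[background])
  res <- list(phase = out, residual = 0, iterations = 0L)
  class(res) <- "unwrapped_phase"
  res
}

#' Convert unwrapped phase to physical thickness
#'
#' \code{h = phase * lambda / (2*pi * (n_sample - n_medium))}: the optical
#' path difference of a transmission phase object of uniform internal index.
#'
#' @param phase \code{unwrapped_phase} or phase matrix, rad
#' @param wavelength um
#' @param n_sample,n_medium refractive indices (must differ)
#' @return thickness map, um
#' @examples
#' phase_to_thickness(2 * pi, 0.532, 1.5915, 1.334) # 2.066 um
#' @export
phase_to_thickness <- function(phase, wavelength, n_sample, n_medium) {
  if (n_sample == n_medium) {
    stop("zero optical contrast: n_sample equals n_medium")
  }
  p <- if (inherits(phase, "unwrapped_phase")) phase$phase else phase
  p * wavelength / (2 * pi * (n_sample - n_medium))
}
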