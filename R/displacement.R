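#' Fit per-pixel displacement waveforms over the vibration cycle
#'
#' Per pixel, linear least squares of the per-bin thickness against the bin
#' vibration phases: \code{h_j = c0 + c1 sin(psi_j) + c2 cos(psi_j)}.  Under
#' the compression-only deformation convention (thickness = h0 minus a
#' half-offset sinusoid), the peak-to-trough oscillation amplitude is
#' \code{delta = 2 sqrt(c1^2 + c2^2)} and the undeformed thickness is
#' \code{h0 = c0 + delta/2}.  The amplitude is invariant to a cyclic
#' relabeling of the bins (only the reported oscillation phase shifts).
#'
#' @param series a \code{thickness_series} (from
#'   \code{\link{reconstruct_stack}}) or a list with \code{maps} (list of
#'   thickness matrices, um) and \code{psi} (bin phases, rad; at least 3
#'   distinct)
#' @param quality optional per-pixel validity mask (defaults to the series
#'   mask if present, else all pixels)
#' @return a \code{displacement_map}: \code{amplitude} (delta, um),
#'   \code{phase} (rad), \code{h0_est} (um), \code{residual} (per-pixel rms,
#'   um), \code{valid} mask
#' @export
fit_displacement <- function(series, quality = NULL) {
  maps <- series$maps
  psi <- series$psi
  J <- length(maps)
  if (J < 3 || length(unique(round(psi, 12))) < 3) {
    stop("need at least 3 bins with distinct vibration phases")
  }
  d <- dim(maps[[1]])
  X <- cbind(1, sin(psi), cos(psi))
  Y <- vapply(maps, as.vector, numeric(prod(d))) # pixels x bins
  coef <- t(solve(crossprod(X), crossprod(X, t(Y))))
  c0 <- coef[, 1]; c1 <- coef[, 2]; c2 <- coef[, 3]
  amp <- sqrt(c1^2 + c2^2)
  delta <- 2 * amp
  h0 <- c0 + amp
  resid <- Y - coef %*% t(X)
  rms <- sqrt(rowSums(resid^2) / max(1, J - 3))
  valid <- if (!is.null(quality)) quality else
    if (!is.null(series$mask)) series$mask else matrix(TRUE, d[1], d[2])
  valid <- valid & matrix(h0 > 0, d[1], d[2]) &
    matrix(delta < pmax(h0, .Machine$double.eps), d[1], d[2])
  out <- list(amplitude = matrix(delta, d[1], d[2]),
              phase = matrix(atan2(c2, c1), d[1], d[2]),
              h0_est = matrix(h0, d[1], d[2]),
              residual = matrix(rms, d[1], d[2]),
              valid = valid,
              pixel_pitch = series$pixel_pitch)
  class(out) <- "displacement_map"
  out
}

#' @export
print.displacement_map <- function(x, ...) {
  cat(sprintf(
    "<displacement_map> %d x %d px  delta max %.4g um  h0 max %.4g um\n",
    nrow(x$amplitude), ncol(x$amplitude), max(x$amplitude), max(x$h0_est)))
  invisible(x)
}
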