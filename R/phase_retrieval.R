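#' Least-squares phase retrieval from phase-stepped interferograms
#'
#' Per pixel, fits \code{I_k = A + B cos(theta_k) + C sin(theta_k)} by linear
#' least squares over the reference phases \code{theta_k} and returns the
#' wrapped phase \code{atan2(-C, B)} in \code{(-pi, pi]}, the fringe
#' amplitude \code{sqrt(B^2 + C^2)}, the visibility \code{amplitude / A} and
#' a per-pixel quality weight in \code{[0, 1]} derived from the fit
#' residual.  The least-squares formulation tolerates non-uniform phase
#' steps; the estimate is exactly invariant to a global intensity scale and
#' offset.
#'
#' @param frames \code{[rows, cols, k]} array of interferograms (one bin)
#' @param theta reference phases, rad (length = number of frames; at least 3
#'   distinct values required)
#' @param visibility_floor pixels with visibility below this get quality 0
#' @return a \code{wrapped_phase}: \code{phase}, \code{amplitude},
#'   \code{visibility}, \code{quality}
#' @export
retrieve_phase <- function(frames, theta, visibility_floor = 0.05) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(theta))
  K <- length(theta)
  if (K < 3 || length(unique(round(theta %% (2 * pi), 12))) < 3) {
    stop("need at least 3 frames with 3 distinct reference phases")
  }
  d <- dim(frames)[1:2]
  X <- cbind(1, cos(theta), sin(theta))
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    stop("rank-deficient phase-step design (degenerate theta values)")
  }
  Y <- matrix(frames, nrow = prod(d), ncol = K) # pixels x frames
  coef <- t(solve(XtX, crossprod(X, t(Y))))     # pixels x 3
  A <- coef[, 1]; B <- coef[, 2]; C <- coef[, 3]
  resid <- Y - coef %*% t(X)
  sig <- sqrt(rowSums(resid^2) / max(1, K - 3))
  amp <- sqrt(B^2 + C^2)
  vis <- ifelse(A > 0, amp / A, 0)
  quality <- ifelse(amp > 0, amp^2 / (amp^2 + sig^2), 0)
  quality[vis < visibility_floor] <- 0
  ph <- atan2(-C, B)
  # principal interval (-pi, pi]: atan2 returns [-pi, pi]; fold -pi up
  ph[ph <= -pi] <- pi
  out <- list(phase = matrix(ph, d[1], d[2]),
              amplitude = matrix(amp, d[1], d[2]),
              visibility = matrix(vis, d[1], d[2]),
              quality = matrix(quality, d[1], d[2]))
  class(out) <- "wrapped_phase"
  out
}

#' @export
print.wrapped_phase <- function(x, ...) {
  cat(sprintf("<wrapped_phase> %d x %d px  phase in [%.3f, %.3f] rad\n",
              nrow(x$phase), ncol(x$phase), min(x$phase), max(x$phase)))
  invisible(x)
}
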