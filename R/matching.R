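#' Periodic Daubechies-4 discrete wavelet transform (1-D)
#'
#' Multi-level pyramid DWT with periodic boundary handling; returns the
#' detail coefficients of all levels concatenated (coarsest approximation is
#' dropped).  Exposed as the feature transform of the 1-D series matcher
#' (see \code{\link{match_step_offset}}).
#'
#' @param x numeric vector (odd lengths are truncated by one sample per
#'   level)
#' @param levels decomposition depth (default 3)
#' @return numeric vector of concatenated detail coefficients
#' @export
dwt_db4 <- function(x, levels = 3) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)) # scaling filter
  g <- rev(h) * c(1, -1, 1, -1)                          # wavelet filter
  details <- list()
  a <- x
  for (l in seq_len(levels)) {
    n <- length(a)
    if (n < 4) break
    if (n %% 2 == 1) a <- a[-n]
    n <- length(a)
    idx <- outer(seq(1, n, by = 2) - 1, 0:3, "+") %% n + 1
    am <- matrix(a[idx], ncol = 4)
    details[[l]] <- as.vector(am %*% g)
    a <- as.vector(am %*% h)
  }
  unlist(details)
}

# cyclic shift: y[j] = x[(j + s) mod n]
cyc_shift <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) x else c(x[(s + 1):n], x[1:s])
}

#' Recover per-step cyclic frame offsets
#'
#' Each phase step samples the same vibration cycle, but the cycle position
#' at which a step's frame sequence starts may differ.  For each step
#' \code{k > 0} this finds the cyclic shift \code{s_k} such that frame
#' \code{(j + s_k) mod F} of step \code{k} lies at the same vibration phase
#' as frame \code{j} of step 0 (so that \code{\link{bin_frames}} groups
#' co-phased frames).
#'
#' The temporally centered intensity of any pixel follows
#' \code{Re(exp(i*theta_k) * u_x(psi))} for a step-independent complex
#' vibration modulation \code{u_x}; the reference phase \code{theta_k}
#' rotates it differently at every step, so directly correlating two steps
#' is sign-ambiguous (lags \code{s} and \code{s + F/2} become
#' indistinguishable when the rotated amplitudes have opposite signs).  The
#' matcher therefore proceeds progressively: from the steps aligned so far
#' it estimates both quadratures of \code{u_x} per pixel and vibration
#' sample by least squares over the known \code{theta_k}, predicts the next
#' step's centered frame sequence, and scores every cyclic lag by the
#' normalized cross-correlation (computed over the vibration cycle by FFT
#' and summed over pixels) between the observed and predicted sequences.
#' This is the frame-sequence analogue of pairing each interferogram with
#' its most likely phase-shifted partner.
#'
#' Vibration-free (constant) sequences are ambiguous: the shift defaults to
#' 0 and the result flags those steps, with a warning.
#'
#' @param stack an \code{interferogram_stack}
#' @return \code{list(shifts, scores, ambiguous)}: integer shifts (first
#'   element 0), the winning normalized score per step, and the ambiguity
#'   flags
#' @export
match_step_offset <- function(stack) {
  validate_stack(stack)
  K <- stack$plan$n_steps
  Fn <- stack$plan$frames_per_step
  if (Fn < 4) stop("need at least 4 frames per step to match offsets")
  d2 <- prod(dim(stack$frames[[1]])[1:2])
  theta <- stack$theta
  # centered per-step data, frames as rows: F x Npix
  center <- function(k) {
    M <- t(matrix(stack$frames[[k]], d2, Fn))
    M - rep(colMeans(M), each = Fn)
  }
  shifts <- integer(K)
  scores <- numeric(K)
  ambiguous <- logical(K)
  scores[1] <- 1
  A0 <- center(1)
  scale0 <- max(sqrt(mean(A0^2)), 1e-12)
  d <- dim(A0)

  # The lag estimator: the cyclic cross-correlation of observed and
  # predicted sequences is (to first order in the modulation depth) a
  # shifted copy of the near-sinusoidal vibration autocorrelation, so the
  # lag is read off the phase of its fundamental: each pixel contributes
  # fft(O_x)[1] * conj(fft(P_x)[1]) = gamma_x^2 |g1|^2 exp(-2*pi*i*s/F)
  # with a sign-definite (squared) amplitude, making the pixel sum
  # coherent.  Phase estimation discriminates sub-lag detail that a
  # discrete correlation argmax cannot at realistic noise levels.
  lag_of <- function(O, P) {
    zO <- stats::mvfft(O)[2, ]
    zP <- stats::mvfft(P)[2, ]
    z <- sum(zO * Conj(zP))
    den <- sqrt(sum(Mod(zO)^2) * sum(Mod(zP)^2))
    s_frac <- (-Fn * Arg(z) / (2 * pi)) %% Fn
    list(s = as.integer(round(s_frac)) %% Fn,
         score = if (den > 0) Mod(z) / den else 0)
  }
  shift_rows <- function(M, s) {
    if (s == 0) M else M[c((s + 1):Fn, 1:s), , drop = FALSE]
  }

  # running normal-equation sums for the per-(pixel, sample) quadratures
  Scc <- cos(theta[1])^2
  Sss <- sin(theta[1])^2
  Scs <- -cos(theta[1]) * sin(theta[1])
  S1 <- cos(theta[1]) * A0
  S2 <- -sin(theta[1]) * A0
  n_aligned <- 1L
  predict_step <- function(k) {
    det <- Scc * Sss - Scs^2
    if (n_aligned < 2L || det < 1e-10 * (Scc + Sss)^2) {
      A0 # single usable step: predict by the small adjacent-theta rotation
    } else {
      U1 <- (Sss * S1 - Scs * S2) / det
      U2 <- (Scc * S2 - Scs * S1) / det
      cos(theta[k]) * U1 - sin(theta[k]) * U2
    }
  }
  add_step <- function(k, O, sgn) {
    ct <- cos(theta[k]); st <- sin(theta[k])
    Scc <<- Scc + sgn * ct^2
    Sss <<- Sss + sgn * st^2
    Scs <<- Scs - sgn * ct * st
    Ak <- shift_rows(O, shifts[k])
    S1 <<- S1 + sgn * ct * Ak
    S2 <<- S2 - sgn * st * Ak
    n_aligned <<- n_aligned + sgn
  }

  # progressive pass
  for (k in seq_len(K)[-1]) {
    O <- center(k)
    if (sqrt(mean(O^2)) < 1e-9 * scale0) {
      ambiguous[k] <- TRUE
      next
    }
    est <- lag_of(O, predict_step(k))
    shifts[k] <- est$s
    scores[k] <- est$score
    add_step(k, O, 1)
  }
  # leave-one-out refinement: re-estimate each shift against the model
  # built from all other aligned steps, until stable
  for (pass in 1:3) {
    changed <- FALSE
    for (k in seq_len(K)[-1]) {
      if (ambiguous[k]) next
      O <- center(k)
      add_step(k, O, -1)
      est <- lag_of(O, predict_step(k))
      if (est$s != shifts[k]) changed <- TRUE
      shifts[k] <- est$s
      scores[k] <- est$score
      add_step(k, O, 1)
    }
    if (!changed) break
  }
  if (any(ambiguous)) {
    warning(sprintf(
      "vibration-free sequence in step(s) %s: offset ambiguous, defaulting to 0",
      paste(which(ambiguous), collapse = ", ")))
  }
  list(shifts = shifts, scores = scores, ambiguous = ambiguous)
}
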