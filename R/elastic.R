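#' Elastic model parameters
#'
#' Parameters of the linear-elastic response linking acoustic pressure to
#' membrane deflection.  The default model is the local elastic-column
#' (small-indentation half-space surrogate)
#' \code{w = p0 * h0 * (1 - nu^2) / E}; a positive membrane coupling
#' \code{lateral_coupling} T (N/m) adds a two-dimensional term
#' \code{-T * laplacian(w)} coupling neighbouring pixels.
#'
#' @param poisson_ratio nu, default 0.5 (incompressible)
#' @param lateral_coupling membrane tension T, N/m (0 = purely local model)
#' @param p0 acoustic pressure amplitude, Pa (required for inversion; often
#'   supplied by \code{\link{calibrate_pressure}})
#' @param tol relative-update convergence tolerance of the iterative
#'   inversion
#' @param max_iter iteration cap
#' @return an \code{elastic_params}
#' @export
elastic_params <- function(poisson_ratio = 0.5, lateral_coupling = 0,
                           p0 = NA_real_, tol = 1e-8, max_iter = 100) {
  stopifnot(poisson_ratio >= 0, poisson_ratio < 0.5 + 1e-9,
            lateral_coupling >= 0)
  out <- list(poisson_ratio = poisson_ratio,
              lateral_coupling = lateral_coupling,
              p0 = p0, tol = tol, max_iter = max_iter)
  class(out) <- "elastic_params"
  out
}

# N/m -> Pa*um (grids are in um)
.T_scale <- 1e6

# 5-point Laplacian with zero (Dirichlet) values outside the mask; x in um,
# pixel pitch in um; returns 1/um units times x units
masked_laplacian <- function(x, mask, pitch) {
  d <- dim(x)
  xm <- x
  xm[!mask] <- 0
  up <- rbind(xm[-1, , drop = FALSE], 0)
  dn <- rbind(0, xm[-d[1], , drop = FALSE])
  lf <- cbind(xm[, -1, drop = FALSE], 0)
  rt <- cbind(0, xm[, -d[2], drop = FALSE])
  (up + dn + lf + rt - 4 * xm) / pitch^2
}

#' Forward elastic response: deflection under uniform pressure
#'
#' Solves, on the support (pixels with \code{h0 > 0}) with zero deflection on
#' the boundary,
#' \deqn{\frac{E}{(1-\nu^2)\,h_0} w - T \nabla^2 w = p_0.}
#' With \code{T = 0} this closes pixelwise to
#' \code{w = p0 * h0 * (1 - nu^2) / E}; with \code{T > 0} a sparse SPD
#' system is solved.
#'
#' @param E stiffness field, Pa (matrix)
#' @param h0 undeformed thickness field, um (matrix; support = h0 > 0)
#' @param params \code{\link{elastic_params}} carrying nu, T and p0
#' @param pixel_pitch um per pixel (needed when T > 0)
#' @return deflection amplitude field w, um (0 off the support)
#' @export
elastic_forward <- function(E, h0, params, pixel_pitch = 1) {
  stopifnot(all(dim(E) == dim(h0)))
  if (is.na(params$p0)) stop("p0 must be set for the forward model")
  mask <- h0 > 0
  if (any(E[mask] <= 0)) {
    idx <- which(mask & E <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("singular system: non-positive stiffness at pixel (%d, %d)",
                 idx[1], idx[2]))
  }
  nu2 <- 1 - params$poisson_ratio^2
  w <- matrix(0, nrow(E), ncol(E))
  if (params$lateral_coupling == 0) {
    w[mask] <- params$p0 * h0[mask] * nu2 / E[mask]
    return(w)
  }
  Tp <- params$lateral_coupling * .T_scale # Pa*um
  idx <- which(mask)
  n <- length(idx)
  pos <- matrix(NA_integer_, nrow(E), ncol(E))
  pos[idx] <- seq_len(n)
  k <- E[idx] / (nu2 * h0[idx]) # Pa/um
  ip2 <- 1 / pixel_pitch^2
  rows <- idx %% nrow(E); rows[rows == 0] <- nrow(E)
  cols <- (idx - 1) %/% nrow(E) + 1
  ii <- seq_len(n); jj <- seq_len(n); vv <- k + 4 * Tp * ip2
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1 & r2 <= nrow(E) & c2 >= 1 & c2 <= ncol(E)
    nb <- rep(NA_integer_, n)
    nb[ok] <- pos[cbind(r2[ok], c2[ok])]
    has <- !is.na(nb)
    ii <- c(ii, which(has)); jj <- c(jj, nb[has])
    vv <- c(vv, rep(-Tp * ip2, sum(has)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  sol <- Matrix::solve(A, rep(params$p0, n))
  w[idx] <- as.numeric(sol)
  w
}

#' Invert the elastic model for a per-pixel stiffness map
#'
#' With \code{T = 0} the inversion closes in one step:
#' \code{E = p0 * h0 * (1 - nu^2) / delta}.  With \code{T > 0}, the
#' initializer \code{E = (1 - nu^2) * h0 * (p0 + T * laplacian(delta)) /
#' delta} is refined by damped fixed-point iteration through
#' \code{\link{elastic_forward}} until the relative update drops below
#' \code{params$tol}.  Pixels whose displacement falls below the noise floor
#' are masked, never extrapolated.
#'
#' @param disp a \code{\link{fit_displacement}} result (\code{displacement_map})
#' @param params \code{\link{elastic_params}} with \code{p0} set (directly or
#'   via \code{\link{calibrate_pressure}})
#' @param noise_floor displacement threshold, um; default 3x the median
#'   per-pixel fit residual (a data-driven floor)
#' @param pixel_pitch um per pixel (needed when T > 0)
#' @return a \code{stiffness_map}: \code{E} (Pa), \code{mask}, and a
#'   \code{summary} list (mean, sd, n_pixels over the mask)
#' @export
invert_stiffness <- function(disp, params, noise_floor = NULL,
                             pixel_pitch = NULL) {
  stopifnot(inherits(disp, "displacement_map"))
  if (is.na(params$p0) || params$p0 <= 0) {
    stop("p0 must be set (supply it or run calibrate_pressure)")
  }
  if (is.null(pixel_pitch)) pixel_pitch <- disp$pixel_pitch
  delta <- disp$amplitude
  h0 <- disp$h0_est
  if (is.null(noise_floor)) {
    med <- stats::median(disp$residual[disp$valid], na.rm = TRUE)
    noise_floor <- 3 * med
  }
  mask <- disp$valid & delta > noise_floor & h0 > 0
  if (!any(mask)) stop("all pixels masked: nothing to invert")
  nu2 <- 1 - params$poisson_ratio^2
  E <- matrix(NA_real_, nrow(delta), ncol(delta))
  if (params$lateral_coupling == 0) {
    E[mask] <- params$p0 * h0[mask] * nu2 / delta[mask]
  } else {
    Tp <- params$lateral_coupling * .T_scale
    lap <- masked_laplacian(delta, mask, pixel_pitch)
    p_eff <- pmax(params$p0 + Tp * lap[mask], 0.05 * params$p0)
    Ev <- nu2 * h0[mask] * p_eff / delta[mask]
    h0m <- matrix(0, nrow(delta), ncol(delta)); h0m[mask] <- h0[mask]
    Em <- matrix(0, nrow(delta), ncol(delta))
    hist <- numeric(0)
    damp <- 0.7
    for (it in seq_len(params$max_iter)) {
      Em[mask] <- Ev
      w <- elastic_forward(Em, h0m, params, pixel_pitch)
      ratio <- w[mask] / delta[mask]
      Ev_new <- Ev * (1 - damp + damp * ratio)
      upd <- max(abs(Ev_new - Ev) / Ev)
      hist <- c(hist, upd)
      Ev <- Ev_new
      if (upd < params$tol) break
    }
    if (hist[length(hist)] >= params$tol) {
      stop(sprintf(
        "stiffness inversion did not converge in %d iterations (last update %.3g; history: %s)",
        params$max_iter, hist[length(hist)],
        paste(signif(utils::tail(hist, 5), 3), collapse = ", ")))
    }
    E[mask] <- Ev
  }
  vals <- E[mask]
  out <- list(E = E, mask = mask,
              summary = list(mean = mean(vals), sd = stats::sd(vals),
                             n_pixels = sum(mask), p0 = params$p0,
                             poisson_ratio = params$poisson_ratio,
                             lateral_coupling = params$lateral_coupling),
              pixel_pitch = pixel_pitch)
  class(out) <- "stiffness_map"
  out
}

#' @export
print.stiffness_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<stiffness_map> E = %.4g +/- %.3g Pa over %d px (p0 = %.3g Pa)\n",
              s$mean, s$sd, s$n_pixels, s$p0))
  invisible(x)
}

#' Calibrate the acoustic pressure from a reference object
#'
#' Given the measured displacement of a reference object of known stiffness
#' (the reference-bead calibration of the instrument), recovers the pressure
#' amplitude from the local model:
#' \code{p0 = median over mask of E_ref * delta / ((1 - nu^2) * h0)}.
#'
#' @param disp_ref \code{displacement_map} of the reference object
#' @param E_ref known reference stiffness, Pa
#' @param params \code{\link{elastic_params}} (nu is used; T ignored: the
#'   reference model is local)
#' @param noise_floor displacement mask threshold as in
#'   \code{\link{invert_stiffness}}
#' @return \code{list(p0, dispersion, n_pixels)}; \code{dispersion} is the
#'   relative median absolute deviation of the per-pixel pressure estimates
#' @export
calibrate_pressure <- function(disp_ref, E_ref, params = elastic_params(),
                               noise_floor = NULL) {
  stopifnot(inherits(disp_ref, "displacement_map"), E_ref > 0)
  if (is.null(noise_floor)) {
    med <- stats::median(disp_ref$residual[disp_ref$valid], na.rm = TRUE)
    noise_floor <- 3 * med
  }
  mask <- disp_ref$valid & disp_ref$amplitude > noise_floor &
    disp_ref$h0_est > 0
  if (!any(mask)) stop("empty calibration mask")
  nu2 <- 1 - params$poisson_ratio^2
  p_px <- E_ref * disp_ref$amplitude[mask] / (nu2 * disp_ref$h0_est[mask])
  p0 <- stats::median(p_px)
  list(p0 = p0,
       dispersion = stats::mad(p_px, center = p0) / p0,
       n_pixels = sum(mask))
}
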