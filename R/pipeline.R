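#' Reconstruct per-bin thickness maps from a raw interferogram stack
#'
#' The full reconstruction chain: wavelet frame matching (optional),
#' stroboscopic binning, per-frame denoising (optional), least-squares phase
#' retrieval per bin, DCT-Poisson/PCG phase unwrapping, blank subtraction
#' (optional) and phase-to-thickness conversion.
#'
#' @param stack an \code{interferogram_stack}
#' @param shifts \code{"match"} (default) to estimate per-step offsets with
#'   \code{\link{match_step_offset}}, \code{"none"} for zero shifts, or an
#'   integer vector
#' @param denoise_sigma per-frame noise SD for
#'   \code{\link{denoise_frame}}; 0 (default) skips denoising
#' @param lowpass_sigma Gaussian low-pass width (pixels) applied to each
#'   interferogram before phase retrieval; 0 (default) disables.  A fast
#'   noise filter for oversampled fringes (phase gradients well below
#'   1 rad/pixel): frame noise drops by roughly \code{2*sigma*sqrt(pi)}
#'   while the fringe signal is virtually untouched.  Use
#'   \code{denoise_sigma} (block-matching collaborative filtering) when
#'   fringes are close to Nyquist
#' @param blank optional blank (sample-free) unwrapped phase to subtract
#' @param visibility_floor masking floor for \code{\link{retrieve_phase}}
#' @param unwrap_tol,unwrap_max_iter PCG controls for
#'   \code{\link{unwrap_phase}}
#' @return a \code{thickness_series}: \code{maps} (list of per-bin thickness
#'   matrices, um), \code{psi} (bin phases), \code{quality} (mean quality
#'   map), \code{unwrap_residuals}, and optics metadata
#' @export
reconstruct_stack <- function(stack, shifts = "match", denoise_sigma = 0,
                              lowpass_sigma = 0, blank = NULL,
                              visibility_floor = 0.05,
                              unwrap_tol = 1e-8, unwrap_max_iter = 500) {
  validate_stack(stack)
  if (identical(shifts, "match")) {
    shifts <- match_step_offset(stack)$shifts
  } else if (identical(shifts, "none")) {
    shifts <- rep(0L, stack$plan$n_steps)
  }
  binset <- bin_frames(stack, shifts)
  Fn <- length(binset$bins)
  lam <- stack$optics$wavelength
  maps <- vector("list", Fn)
  qsum <- 0
  resids <- numeric(Fn)
  for (j in seq_len(Fn)) {
    frames <- binset$bins[[j]]
    if (denoise_sigma > 0 || lowpass_sigma > 0) {
      for (k in seq_len(dim(frames)[3])) {
        f <- frames[, , k]
        if (denoise_sigma > 0) f <- denoise_frame(f, denoise_sigma)
        if (lowpass_sigma > 0) f <- fft_gauss_smooth(f, lowpass_sigma)
        frames[, , k] <- f
      }
    }
    wp <- retrieve_phase(frames, binset$theta,
                         visibility_floor = visibility_floor)
    up <- unwrap_phase(wp, tol = unwrap_tol, max_iter = unwrap_max_iter)
    if (!is.null(blank)) up <- reference_subtract(up, blank)
    maps[[j]] <- phase_to_thickness(up, lam, stack$n_sample, stack$n_medium)
    qsum <- qsum + wp$quality
    resids[j] <- up$residual
  }
  out <- list(maps = maps, psi = binset$psi, quality = qsum / Fn,
              unwrap_residuals = resids, shifts = shifts,
              wavelength = lam, n_sample = stack$n_sample,
              n_medium = stack$n_medium, pixel_pitch = stack$pixel_pitch)
  class(out) <- "thickness_series"
  out
}

#' @export
print.thickness_series <- function(x, ...) {
  cat(sprintf(
    "<thickness_series> %d bins of %d x %d px  thickness max %.4g um\n",
    length(x$maps), nrow(x$maps[[1]]), ncol(x$maps[[1]]),
    max(vapply(x$maps, max, numeric(1)))))
  invisible(x)
}

#' Full acquisition-to-stiffness pipeline
#'
#' Convenience wrapper chaining \code{\link{acquire_stack}},
#' \code{\link{reconstruct_stack}}, \code{\link{fit_displacement}} and
#' \code{\link{invert_stiffness}} for a simulated scene.  \code{params$p0}
#' must be set (directly, or calibrate first on a reference object with
#' \code{\link{calibrate_pressure}}).
#'
#' @param scene a \code{sample_scene}
#' @param drive,plan,optics,model simulator settings (see
#'   \code{\link{acquire_stack}})
#' @param params \code{\link{elastic_params}} used for the inversion; if its
#'   \code{p0} is \code{NA} the drive amplitude is used (closed-loop
#'   simulation studies)
#' @param seed master seed
#' @param step_offsets forwarded to \code{\link{acquire_stack}}
#' @param denoise_sigma,lowpass_sigma forwarded to
#'   \code{\link{reconstruct_stack}}
#' @param shifts forwarded to \code{\link{reconstruct_stack}}
#' @return list with \code{stack}, \code{series}, \code{displacement},
#'   \code{stiffness}
#' @export
holo_pipeline <- function(scene, drive = acoustic_drive(),
                          plan = acquisition_plan(),
                          optics = optical_config(),
                          model = elastic_params(),
                          params = NULL, seed = 1,
                          step_offsets = "none", denoise_sigma = 0,
                          lowpass_sigma = 0, shifts = "match") {
  if (is.null(params)) params <- model
  if (is.na(params$p0)) params$p0 <- drive$pressure_amplitude
  stack <- acquire_stack(scene, drive, plan, optics, model, seed,
                         step_offsets)
  series <- reconstruct_stack(stack, shifts = shifts,
                              denoise_sigma = denoise_sigma,
                              lowpass_sigma = lowpass_sigma)
  disp <- fit_displacement(series)
  stiff <- invert_stiffness(disp, params)
  list(stack = stack, series = series, displacement = disp,
       stiffness = stiff)
}
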