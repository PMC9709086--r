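#' Optical configuration of the interferometer
#'
#' Parameters of the simulated phase-shifting Mach-Zehnder interferometer:
#' wavelength (0.527 um for cell work, 0.532 um for bead work), mean fringe
#' intensity and visibility, an optional low-order background aberration
#' phase, the detector full scale (12-bit default) and the noise model.
#'
#' The noise model is \code{list(shot, read_sd)}: per-pixel intensity
#' variance \code{shot * I + read_sd^2} (shot noise proportional to
#' intensity plus additive read noise), applied as Gaussian perturbations.
#'
#' @param wavelength um
#' @param mean_intensity counts (I0)
#' @param visibility fringe visibility V in (0, 1]
#' @param background_phase optional aberration phase field, rad (matrix), or
#'   NULL for none
#' @param noise \code{list(shot =, read_sd =)}; both zero means noise-free
#' @param full_scale detector saturation, counts
#' @return an \code{optical_config}
#' @export
optical_config <- function(wavelength = 0.527, mean_intensity = 1800,
                           visibility = 0.9, background_phase = NULL,
                           noise = list(shot = 0, read_sd = 0),
                           full_scale = 4095) {
  stopifnot(wavelength > 0, mean_intensity > 0,
            visibility > 0, visibility <= 1,
            noise$shot >= 0, noise$read_sd >= 0, full_scale > 0)
  out <- list(wavelength = wavelength, mean_intensity = mean_intensity,
              visibility = visibility, background_phase = background_phase,
              noise = noise, full_scale = full_scale)
  class(out) <- "optical_config"
  out
}

#' Noise parameters for a target intensity SNR
#'
#' Splits the total noise variance implied by an SNR (in dB, relative to the
#' mean intensity) evenly between shot and read contributions, evaluated at
#' the mean intensity.
#'
#' @param mean_intensity counts
#' @param snr_db 20*log10(mean intensity / noise SD); \code{Inf} disables
#'   noise
#' @return \code{list(shot, read_sd)} for \code{\link{optical_config}}
#' @export
noise_for_snr <- function(mean_intensity, snr_db) {
  if (is.infinite(snr_db)) return(list(shot = 0, read_sd = 0))
  v <- (mean_intensity / 10^(snr_db / 20))^2
  list(shot = v / 2 / mean_intensity, read_sd = sqrt(v / 2))
}

#' Acoustic drive settings
#'
#' @param frequency acoustic frequency, Hz (default 1000)
#' @param pressure_amplitude peak pressure p0 at the sample, Pa
#' @param power nominal electrical drive power, W (metadata only; the
#'   conversion from electrical power to pressure is not modelled)
#' @return an \code{acoustic_drive}
#' @export
acoustic_drive <- function(frequency = 1000, pressure_amplitude = 150,
                           power = 0.05) {
  stopifnot(frequency > 0, pressure_amplitude >= 0)
  out <- list(frequency = frequency,
              pressure_amplitude = pressure_amplitude, power = power)
  class(out) <- "acoustic_drive"
  out
}

#' Acquisition plan: phase stepping and stroboscopic sampling
#'
#' Default plan: 20 piezo steps of pi/10 rad, 50 frames per step, camera
#' frame rate \code{f_a + delta_f} with \code{delta_f = f_a /
#' (frames_per_step - 1)} so that the frames of one step uniformly tile one
#' vibration cycle (per-frame vibration-phase slip of 2*pi/frames_per_step).
#'
#' @param n_steps number of reference-phase steps
#' @param step_phase phase increment per step, rad
#' @param frames_per_step frames acquired at each step
#' @param delta_f stroboscopic frequency offset, Hz; \code{NULL} selects the
#'   uniform-tiling default for a given drive frequency at acquisition time
#' @return an \code{acquisition_plan}
#' @export
acquisition_plan <- function(n_steps = 20, step_phase = pi / 10,
                             frames_per_step = 50, delta_f = NULL) {
  stopifnot(n_steps >= 2, frames_per_step >= 3, step_phase > 0)
  if (n_steps * step_phase < 2 * pi - 1e-12) {
    stop("phase steps must span at least 2*pi")
  }
  out <- list(n_steps = as.integer(n_steps), step_phase = step_phase,
              frames_per_step = as.integer(frames_per_step),
              delta_f = delta_f)
  class(out) <- "acquisition_plan"
  out
}
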