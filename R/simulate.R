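#' Instantaneous thickness under acoustic load
#'
#' Deforms a scene at vibration phase \code{psi}: the acoustic pressure only
#' compresses, so the instantaneous thickness is
#' \code{h = h0 - w * (1 + sin(psi)) / 2}, where \code{w} is the deflection
#' amplitude field from \code{\link{elastic_forward}}.  Deflection peaks at
#' \code{sin(psi) = +1}; at \code{sin(psi) = -1} the sample is undeformed.
#'
#' @param scene a \code{sample_scene}
#' @param drive an \code{acoustic_drive} (supplies p0)
#' @param model \code{\link{elastic_params}} (Poisson ratio, membrane
#'   coupling); its \code{p0} is taken from \code{drive}
#' @param psi vibration phase, rad, in \code{[0, 2*pi)}
#' @return thickness field, um
#' @export
deform_thickness <- function(scene, drive, model = elastic_params(),
                             psi = 0) {
  validate_scene(scene)
  stopifnot(psi >= 0, psi < 2 * pi)
  w <- deflection_field(scene, drive, model)
  scene$h0 - w * (1 + sin(psi)) / 2
}

# deflection amplitude field for a scene under a drive (um), with the
# unphysical-compression guard shared by all simulator entry points
deflection_field <- function(scene, drive, model) {
  model$p0 <- drive$pressure_amplitude
  w <- elastic_forward(scene$E_true, scene$h0, model,
                       pixel_pitch = scene$pixel_pitch)
  bad <- scene$support & (w >= scene$h0)
  if (any(bad)) {
    stop(sprintf(
      "unphysical full compression: deflection >= thickness at %d pixel(s); reduce p0",
      sum(bad)))
  }
  w
}

#' Render one interferogram
#'
#' Noise-free fringe intensity
#' \code{I = I0 * (1 + V * cos(phi + theta + phi_bg))} with the sample phase
#' \code{phi = 2*pi*(n_s - n_m)*h / lambda} (thicker sample, larger phase),
#' then Gaussian shot noise (variance proportional to intensity) and
#' additive read noise, clipped to \code{[0, full_scale]}.  Counts stay
#' continuous; quantization happens only when a stack is written to disk.
#'
#' @param h thickness field, um (non-negative)
#' @param theta reference phase, rad
#' @param optics an \code{optical_config}
#' @param n_sample,n_medium refractive indices
#' @param seed seed for the noise draw (ignored when noise is off)
#' @return intensity image, counts
#' @export
render_interferogram <- function(h, theta, optics, n_sample, n_medium,
                                 seed = 1) {
  if (any(h < 0)) stop("negative thickness input")
  phi <- 2 * pi * (n_sample - n_medium) * h / optics$wavelength
  if (!is.null(optics$background_phase)) phi <- phi + optics$background_phase
  I <- optics$mean_intensity * (1 + optics$visibility * cos(phi + theta))
  ns <- optics$noise
  if (ns$shot > 0 || ns$read_sd > 0) {
    I <- with_seed(seed, {
      sd <- sqrt(ns$shot * pmax(I, 0) + ns$read_sd^2)
      I + stats::rnorm(length(I), 0, 1) * sd
    })
    dim(I) <- dim(h)
  }
  pmin(pmax(I, 0), optics$full_scale)
}

#' Acquire a phase-stepped, stroboscopically sampled interferogram stack
#'
#' Frame \code{j} of step \code{k} (both 0-based) is rendered at time
#' \code{t = (k*F + j) / frame_rate} with reference phase
#' \code{theta_k = k * step_phase} and vibration phase
#' \code{psi = 2*pi*f_a*t mod 2*pi} (plus an optional per-step cyclic start
#' offset, expressed in frame slips, to exercise the frame-matching stage).
#' The camera runs at \code{f_a + delta_f}; the default \code{delta_f}
#' makes the \code{F} frames of a step tile one vibration cycle uniformly.
#'
#' @param scene a \code{sample_scene}
#' @param drive an \code{acoustic_drive}
#' @param plan an \code{acquisition_plan}
#' @param optics an \code{optical_config}
#' @param model \code{\link{elastic_params}} for the deformation
#' @param seed master seed (per-frame noise streams derived by counter)
#' @param step_offsets \code{"none"} (default), \code{"random"}, or an
#'   integer vector of per-step cyclic start offsets in frames
#' @return an \code{interferogram_stack}: \code{frames} is a list over steps
#'   of \code{[rows, cols, frame]} arrays; carries \code{theta} (rad per
#'   step), \code{timestamps} (s, strictly increasing), the true per-frame
#'   vibration phases \code{psi} (simulation ground truth), the plan, optics
#'   and scene metadata
#' @export
acquire_stack <- function(scene, drive, plan = acquisition_plan(),
                          optics = optical_config(), model = elastic_params(),
                          seed = 1, step_offsets = "none") {
  validate_scene(scene)
  Fn <- plan$frames_per_step
  K <- plan$n_steps
  delta_f <- plan$delta_f
  if (is.null(delta_f)) delta_f <- drive$frequency / (Fn - 1)
  if (delta_f == 0) stop("delta_f must be nonzero: no stroboscopic sweep")
  frame_rate <- drive$frequency + delta_f
  if (frame_rate == drive$frequency) stop("frame rate equals drive frequency")

  if (identical(step_offsets, "none")) {
    off <- rep(0L, K)
  } else if (identical(step_offsets, "random")) {
    off <- with_seed(child_seed(seed, 0), sample(0:(Fn - 1), K, replace = TRUE))
    off[1] <- 0L
  } else {
    stopifnot(length(step_offsets) == K)
    off <- as.integer(step_offsets) %% Fn
  }

  w <- deflection_field(scene, drive, model)
  theta <- (seq_len(K) - 1) * plan$step_phase
  d <- dim(scene$h0)
  frames <- vector("list", K)
  timestamps <- matrix(0, Fn, K)
  psi_true <- matrix(0, Fn, K)
  ctr <- 1L
  for (k in seq_len(K)) {
    arr <- array(0, c(d[1], d[2], Fn))
    for (j in seq_len(Fn)) {
      t <- ((k - 1) * Fn + (j - 1)) / frame_rate
      psi <- (2 * pi * drive$frequency * (t + off[k] / frame_rate)) %% (2 * pi)
      h <- scene$h0 - w * (1 + sin(psi)) / 2
      arr[, , j] <- render_interferogram(h, theta[k], optics,
                                         scene$n_sample, scene$n_medium,
                                         seed = child_seed(seed, ctr))
      timestamps[j, k] <- t
      psi_true[j, k] <- psi
      ctr <- ctr + 1L
    }
    frames[[k]] <- arr
  }
  out <- list(frames = frames, theta = theta, timestamps = timestamps,
              psi = psi_true, plan = plan, optics = optics, drive = drive,
              frame_rate = frame_rate, delta_f = delta_f,
              n_sample = scene$n_sample, n_medium = scene$n_medium,
              pixel_pitch = scene$pixel_pitch,
              truth = list(step_offsets = off, deflection = w))
  class(out) <- "interferogram_stack"
  validate_stack(out)
}

#' Validate an interferogram stack
#'
#' @param stack an \code{interferogram_stack}
#' @return the stack, invisibly; errors on violated invariants (frame count,
#'   negative intensities, non-monotone timestamps)
#' @export
validate_stack <- function(stack) {
  stopifnot(inherits(stack, "interferogram_stack"))
  K <- stack$plan$n_steps
  Fn <- stack$plan$frames_per_step
  if (length(stack$frames) != K) stop("stack must hold one array per step")
  nf <- vapply(stack$frames, function(a) dim(a)[3], numeric(1))
  if (!all(nf == Fn)) {
    stop(sprintf("frame count mismatch: expected %d frames/step, found %s",
                 Fn, paste(unique(nf), collapse = ",")))
  }
  if (any(vapply(stack$frames, function(a) any(a < 0), logical(1)))) {
    stop("intensities must be non-negative")
  }
  ts <- as.vector(stack$timestamps)
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
  invisible(stack)
}

#' @export
print.interferogram_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<interferogram_stack> %d steps x %d frames of %d x %d px  (%.4g-%.4g counts)\n",
    x$plan$n_steps, x$plan$frames_per_step, d[1], d[2],
    min(vapply(x$frames, min, numeric(1))),
    max(vapply(x$frames, max, numeric(1)))))
  invisible(x)
}

#' Total number of interferograms in a stack
#' @param stack an \code{interferogram_stack}
#' @return integer count (steps x frames per step)
#' @export
n_frames <- function(stack) {
  stack$plan$n_steps * stack$plan$frames_per_step
}
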