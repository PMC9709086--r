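#' Write an interferogram stack as multi-page TIFF + JSON sidecar
#'
#' Frames are stored in acquisition order as 16-bit grayscale TIFF pages
#' (counts quantized to the nearest integer; the detector full scale is far
#' below the 16-bit range so quantization is the only loss).  The JSON
#' sidecar (\code{<path>.json}) carries the reference phases, timestamps,
#' plan, optics, drive and scene metadata; \code{\link{read_stack}} restores
#' the same dialect losslessly.
#'
#' @param stack an \code{interferogram_stack}
#' @param path output TIFF path (sidecar written beside it)
#' @return \code{path}, invisibly
#' @export
write_stack <- function(stack, path) {
  validate_stack(stack)
  K <- stack$plan$n_steps
  Fn <- stack$plan$frames_per_step
  pages <- vector("list", K * Fn)
  i <- 1L
  for (k in seq_len(K)) {
    for (j in seq_len(Fn)) {
      pages[[i]] <- round(stack$frames[[k]][, , j]) / 65535
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(
    format = "holostiff-stack-v1",
    n_steps = K, frames_per_step = Fn,
    step_phase = stack$plan$step_phase,
    theta = stack$theta,
    timestamps = as.vector(stack$timestamps),
    frame_rate = stack$frame_rate, delta_f = stack$delta_f,
    drive = list(frequency = stack$drive$frequency,
                 pressure_amplitude = stack$drive$pressure_amplitude,
                 power = stack$drive$power),
    optics = list(wavelength = stack$optics$wavelength,
                  mean_intensity = stack$optics$mean_intensity,
                  visibility = stack$optics$visibility,
                  full_scale = stack$optics$full_scale,
                  noise = stack$optics$noise),
    n_sample = stack$n_sample, n_medium = stack$n_medium,
    pixel_pitch = stack$pixel_pitch,
    count_scale = 65535
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an interferogram stack written by \code{\link{write_stack}}
#'
#' @param path TIFF path; the \code{<path>.json} sidecar must exist
#' @return an \code{interferogram_stack}
#' @export
read_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "holostiff-stack-v1")) {
    stop("unrecognized stack dialect: ", meta$format)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  K <- meta$n_steps; Fn <- meta$frames_per_step
  if (length(pages) != K * Fn) {
    stop(sprintf(
      "frame-count mismatch: sidecar declares %d steps x %d frames = %d, TIFF holds %d pages",
      K, Fn, K * Fn, length(pages)))
  }
  ts <- matrix(meta$timestamps, Fn, K)
  if (any(diff(as.vector(ts)) <= 0)) {
    stop("non-monotone timestamps in sidecar")
  }
  d <- dim(pages[[1]])
  frames <- vector("list", K)
  i <- 1L
  for (k in seq_len(K)) {
    arr <- array(0, c(d[1], d[2], Fn))
    for (j in seq_len(Fn)) {
      arr[, , j] <- pages[[i]] * meta$count_scale
      i <- i + 1L
    }
    frames[[k]] <- arr
  }
  plan <- acquisition_plan(n_steps = K, step_phase = meta$step_phase,
                           frames_per_step = Fn, delta_f = meta$delta_f)
  optics <- optical_config(wavelength = meta$optics$wavelength,
                           mean_intensity = meta$optics$mean_intensity,
                           visibility = meta$optics$visibility,
                           noise = as.list(meta$optics$noise),
                           full_scale = meta$optics$full_scale)
  drive <- acoustic_drive(frequency = meta$drive$frequency,
                          pressure_amplitude = meta$drive$pressure_amplitude,
                          power = meta$drive$power)
  out <- list(frames = frames, theta = meta$theta, timestamps = ts,
              psi = NULL, plan = plan, optics = optics, drive = drive,
              frame_rate = meta$frame_rate, delta_f = meta$delta_f,
              n_sample = meta$n_sample, n_medium = meta$n_medium,
              pixel_pitch = meta$pixel_pitch, truth = NULL)
  class(out) <- "interferogram_stack"
  validate_stack(out)
  out
}

#' Write float maps as multi-page 32-bit TIFF + JSON sidecar
#'
#' Physical values (um, Pa, rad) are affinely rescaled into the TIFF
#' sample range; the offset and scale live in the JSON sidecar and
#' \code{\link{read_maps}} restores the original units (to float32
#' precision of the value range).
#'
#' @param maps a matrix or list of matrices (um, Pa, rad ... as produced by
#'   the pipeline)
#' @param path output TIFF path
#' @param meta named list of scalar metadata stored in the sidecar (pixel
#'   pitch, wavelength, summaries, ...)
#' @return \code{path}, invisibly
#' @export
write_maps <- function(maps, path, meta = list()) {
  if (is.matrix(maps)) maps <- list(maps)
  rng <- range(vapply(maps, range, numeric(2)))
  offset <- rng[1]
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  scaled <- lapply(maps, function(m) (m - offset) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, compression = "none")
  meta$format <- "holostiff-maps-v1"
  meta$n_pages <- length(maps)
  meta$map_offset <- offset
  meta$map_scale <- scale
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read maps written by \code{\link{write_maps}}
#'
#' @param path TIFF path
#' @return \code{list(maps = list of matrices, meta = sidecar list)}
#' @export
read_maps <- function(path) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else list()
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(meta$map_scale)) {
    pages <- lapply(pages, function(m) m * meta$map_scale + meta$map_offset)
  }
  list(maps = pages, meta = meta)
}

#' Read or write a run configuration (YAML)
#'
#' A run configuration holds every knob of a simulation/reconstruction run:
#' scene parameters, optics, drive, acquisition plan, elastic model, seeds
#' and the output directory.  It round-trips losslessly through YAML; every
#' pipeline run writes its resolved configuration beside its outputs.
#'
#' @param path YAML file
#' @return named list (class \code{run_config})
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' @rdname read_run_config
#' @param config a \code{run_config} (or plain named list)
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Default run configuration
#'
#' Study-condition defaults: a 5 um soft bead (PAA preset) in water imaged
#' at 0.532 um with 20 x pi/10 phase steps, 50 frames per step, 1 kHz drive.
#'
#' @param scene_type \code{"bead"} or \code{"cell"}
#' @return a \code{run_config} list
#' @export
default_run_config <- function(scene_type = "bead") {
  cfg <- list(
    scene = if (scene_type == "bead") {
      list(type = "bead", diameter = 5, material = "PAA", medium = "water",
           grid = c(128L, 128L), pixel_pitch = 0.05)
    } else {
      list(type = "cell", mean_diameter = 16, mean_thickness = 4,
           base_stiffness = 1080, heterogeneity = 0.13,
           grid = c(128L, 128L), pixel_pitch = 0.18)
    },
    optics = list(wavelength = if (scene_type == "bead") 0.532 else 0.527,
                  mean_intensity = 1800, visibility = 0.9,
                  snr_db = Inf, full_scale = 4095),
    drive = list(frequency = 1000,
                 pressure_amplitude = if (scene_type == "bead") 150 else 60,
                 power = 0.05),
    plan = list(n_steps = 20L, step_phase = pi / 10, frames_per_step = 50L),
    model = list(poisson_ratio = 0.5, lateral_coupling = 0),
    seed = 1L,
    denoise_sigma = 0
  )
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

# materialize simulator objects from a run_config
config_objects <- function(cfg) {
  sc <- cfg$scene
  scene <- if (identical(sc$type, "bead")) {
    bead_scene(sc$diameter, material(sc$material), material(sc$medium),
               grid_shape = unlist(sc$grid), pixel_pitch = sc$pixel_pitch)
  } else {
    cell_scene(mean_diameter = sc$mean_diameter,
               mean_thickness = sc$mean_thickness,
               base_stiffness = sc$base_stiffness,
               heterogeneity = sc$heterogeneity,
               seed = child_seed(cfg$seed, 99),
               grid_shape = unlist(sc$grid), pixel_pitch = sc$pixel_pitch)
  }
  snr <- cfg$optics$snr_db
  if (is.null(snr) || is.character(snr)) snr <- Inf
  optics <- optical_config(
    wavelength = cfg$optics$wavelength,
    mean_intensity = cfg$optics$mean_intensity,
    visibility = cfg$optics$visibility,
    noise = noise_for_snr(cfg$optics$mean_intensity, snr),
    full_scale = cfg$optics$full_scale)
  drive <- acoustic_drive(cfg$drive$frequency, cfg$drive$pressure_amplitude,
                          cfg$drive$power)
  plan <- acquisition_plan(cfg$plan$n_steps, cfg$plan$step_phase,
                           cfg$plan$frames_per_step, cfg$plan$delta_f)
  model <- elastic_params(cfg$model$poisson_ratio, cfg$model$lateral_coupling)
  list(scene = scene, optics = optics, drive = drive, plan = plan,
       model = model)
}
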