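#' Ground-truth phase objects (scenes)
#'
#' A \code{sample_scene} is the ground truth handed to the forward simulator:
#' a projected-thickness field \code{h0} (um), a stiffness field \code{E_true}
#' (Pa), the sample and medium refractive indices and the pixel pitch.
#' Thickness is non-negative everywhere and strictly positive exactly on the
#' support mask; stiffness is positive on the support.
#'
#' @name sample_scene
NULL

new_scene <- function(h0, E_true, n_sample, n_medium, pixel_pitch,
                      label = "scene") {
  support <- h0 > 0
  out <- list(h0 = h0, E_true = E_true, n_sample = n_sample,
              n_medium = n_medium, pixel_pitch = pixel_pitch,
              support = support, label = label)
  class(out) <- "sample_scene"
  validate_scene(out)
}

#' Validate a sample scene
#'
#' Checks the scene invariants: shared field shapes, non-negative thickness,
#' support consistency (\code{h0 > 0} exactly on the mask) and positive
#' stiffness on the support.
#'
#' @param scene a \code{sample_scene}
#' @return the scene, invisibly; errors on violation
#' @export
validate_scene <- function(scene) {
  stopifnot(inherits(scene, "sample_scene"))
  if (!all(dim(scene$h0) == dim(scene$E_true)) ||
      !all(dim(scene$h0) == dim(scene$support))) {
    stop("scene fields must share one shape")
  }
  if (any(scene$h0 < 0)) stop("thickness must be non-negative everywhere")
  if (!identical(scene$h0 > 0, scene$support)) {
    stop("support mask must equal the h0 > 0 region")
  }
  if (any(scene$E_true[scene$support] <= 0)) {
    stop("stiffness must be positive on the support")
  }
  if (scene$pixel_pitch <= 0) stop("pixel pitch must be positive")
  invisible(scene)
}

#' @export
print.sample_scene <- function(x, ...) {
  d <- dim(x$h0)
  cat(sprintf(
    "<sample_scene> %s  %d x %d px @ %.3g um/px  h0 max %.3g um  E mean %.3g Pa\n",
    x$label, d[1], d[2], x$pixel_pitch, max(x$h0),
    mean(x$E_true[x$support])))
  invisible(x)
}

# pixel-center coordinates (um) relative to the grid center
grid_coords <- function(grid_shape, pixel_pitch) {
  y <- (seq_len(grid_shape[1]) - (grid_shape[1] + 1) / 2) * pixel_pitch
  x <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * pixel_pitch
  list(y = y, x = x)
}

#' Spherical reference bead scene
#'
#' Projected (transmission) thickness of a sphere resting on the substrate:
#' \code{h0(r) = 2 sqrt((d/2)^2 - r^2)} for \code{r < d/2}, else 0 — the
#' chord length of the sphere along the optical axis.  Stiffness is uniform
#' at the material's nominal value unless overridden.
#'
#' @param diameter bead diameter, um
#' @param mat sample material (a \code{material} or preset name), default PS
#' @param medium immersion medium, default DI water
#' @param grid_shape image size \code{c(rows, cols)}, pixels
#' @param pixel_pitch um per pixel
#' @param stiffness override of the uniform stiffness, Pa (default the
#'   material's nominal value)
#' @return a \code{sample_scene}
#' @examples
#' sc <- bead_scene(5, grid_shape = c(64, 64), pixel_pitch = 0.1)
#' max(sc$h0)  # 5 (central chord of a 5-um sphere)
#' @export
bead_scene <- function(diameter, mat = material("PS"),
                       medium = material("water"),
                       grid_shape = c(128, 128), pixel_pitch = 0.05,
                       stiffness = NULL) {
  if (is.character(mat)) mat <- material(mat)
  if (is.character(medium)) medium <- material(medium)
  validate_material(mat); validate_material(medium)
  if (diameter <= 0) stop("bead diameter must be positive")
  fov <- grid_shape * pixel_pitch
  if (diameter >= min(fov)) {
    stop(sprintf(
      "bead of diameter %.3g um does not fit the %.3g x %.3g um field of view",
      diameter, fov[1], fov[2]))
  }
  if (is.null(stiffness)) stiffness <- mat$nominal_stiffness
  if (is.na(stiffness) || stiffness <= 0) {
    stop("bead material must carry a positive stiffness")
  }
  g <- grid_coords(grid_shape, pixel_pitch)
  r2 <- outer(g$y^2, g$x^2, "+")
  R <- diameter / 2
  h0 <- matrix(0, grid_shape[1], grid_shape[2])
  inside <- r2 < R^2
  h0[inside] <- 2 * sqrt(R^2 - r2[inside])
  E <- matrix(stiffness, grid_shape[1], grid_shape[2])
  E[!inside] <- stiffness # uniform; masked by support downstream
  new_scene(h0, E, mat$refractive_index, medium$refractive_index,
            pixel_pitch, label = paste0(mat$name, " bead d=", diameter, "um"))
}

# circularly-wrapped Gaussian smoothing via FFT; sigma in pixels
fft_gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  ky <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) / d[1]
  kx <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1)) / d[2]
  H <- exp(-2 * pi^2 * sigma^2 * outer(ky^2, kx^2, "+"))
  Re(fft(fft(x) * H, inverse = TRUE)) / length(x)
}

#' Cell-like blob scene
#'
#' A smooth, compactly supported thickness dome whose boundary is a low-order
#' Fourier perturbation of a circle (the band-limited, slightly elliptical
#' outline of an adherent cell), with a spatially correlated log-normal
#' stiffness field.  \code{mean_thickness} is the average thickness over the
#' support (the dome peaks at 2.5x that value); \code{heterogeneity} is the
#' relative standard deviation of the stiffness field.  Fully reproducible
#' from \code{seed}.
#'
#' @param mean_diameter cell diameter, um
#' @param mean_thickness support-averaged thickness, um
#' @param base_stiffness mean stiffness, Pa
#' @param heterogeneity relative SD of the log-normal stiffness field, in
#'   \code{[0, 1)}
#' @param seed integer seed
#' @param grid_shape,pixel_pitch grid geometry (pixels; um per pixel)
#' @param corr_length stiffness correlation length, um (default
#'   \code{mean_diameter / 10})
#' @param n_sample cytoplasm refractive index (default 1.375)
#' @param medium immersion medium (default DMEM/F12)
#' @return a \code{sample_scene}
#' @export
cell_scene <- function(mean_diameter = 16, mean_thickness = 4,
                       base_stiffness = 1080, heterogeneity = 0.13,
                       seed = 1, grid_shape = c(128, 128),
                       pixel_pitch = 0.18,
                       corr_length = mean_diameter / 10,
                       n_sample = 1.375, medium = material("DMEM/F12")) {
  if (is.character(medium)) medium <- material(medium)
  if (mean_diameter <= 0 || mean_thickness <= 0 || base_stiffness <= 0) {
    stop("all scale parameters must be positive")
  }
  if (heterogeneity < 0 || heterogeneity >= 1) {
    stop("heterogeneity must lie in [0, 1)")
  }
  if (any(grid_shape < 8)) stop("degenerate grid: need at least 8x8 pixels")
  with_seed(seed, {
    g <- grid_coords(grid_shape, pixel_pitch)
    r <- sqrt(outer(g$y^2, g$x^2, "+"))
    phi <- atan2(matrix(g$y, grid_shape[1], grid_shape[2]),
                 matrix(g$x, grid_shape[1], grid_shape[2], byrow = TRUE))
    R0 <- mean_diameter / 2
    # low-order boundary perturbation: modes 2..5, amplitude ~ 1/m
    pert <- matrix(0, grid_shape[1], grid_shape[2])
    for (m in 2:5) {
      a <- stats::rnorm(1, 0, 0.05 / (m - 1))
      b <- stats::rnorm(1, 0, 0.05 / (m - 1))
      pert <- pert + a * cos(m * phi) + b * sin(m * phi)
    }
    Rb <- R0 * pmin(pmax(1 + pert, 0.75), 1.25)
    rho2 <- (r / Rb)^2
    h0 <- matrix(0, grid_shape[1], grid_shape[2])
    inside <- rho2 < 1
    # dome (1 - rho^2)^{3/2}: support mean 2/5 of the peak
    h0[inside] <- 2.5 * mean_thickness * (1 - rho2[inside])^1.5
    if (!any(inside)) stop("cell does not intersect the grid")
    # spatially correlated log-normal stiffness with mean base_stiffness
    if (heterogeneity > 0) {
      G <- fft_gauss_smooth(matrix(stats::rnorm(prod(grid_shape)),
                                   grid_shape[1], grid_shape[2]),
                            corr_length / pixel_pitch)
      G <- (G - mean(G)) / stats::sd(as.vector(G))
      sl <- sqrt(log(1 + heterogeneity^2))
      E <- exp(log(base_stiffness) - sl^2 / 2 + sl * G)
    } else {
      E <- matrix(base_stiffness, grid_shape[1], grid_shape[2])
    }
    new_scene(h0, E, n_sample, medium$refractive_index, pixel_pitch,
              label = sprintf("cell d=%.3gum E=%.3gPa", mean_diameter,
                              base_stiffness))
  })
}

#' Ensemble of scenes from a factory
#'
#' Builds \code{n} independent scenes by calling \code{factory} with child
#' seeds derived deterministically (by counter) from the master seed.
#'
#' @param factory function of one argument (a child seed) returning a
#'   \code{sample_scene}
#' @param n number of scenes (>= 1)
#' @param seed master seed
#' @return list of \code{n} scenes
#' @export
scene_ensemble <- function(factory, n, seed = 1) {
  if (n < 1) stop("ensemble size must be at least 1")
  lapply(seq_len(n), function(i) factory(child_seed(seed, i)))
}

#' Ensemble of jittered bead scenes
#'
#' Draws per-bead diameter and stiffness from normal distributions around the
#' configured means (default: the material's nominal values), matching the
#' bead-to-bead variability of a reference-particle batch.
#'
#' @param n number of beads
#' @param mat,medium materials (presets or names)
#' @param diameter_mean,diameter_sd diameter distribution, um
#' @param stiffness_mean,stiffness_sd stiffness distribution, Pa
#' @param grid_shape,pixel_pitch grid geometry
#' @param seed master seed
#' @return list of \code{sample_scene}
#' @export
bead_ensemble <- function(n, mat = material("PS"), medium = material("water"),
                          diameter_mean = NULL, diameter_sd = 0,
                          stiffness_mean = NULL, stiffness_sd = 0,
                          grid_shape = c(128, 128), pixel_pitch = 0.05,
                          seed = 1) {
  if (is.character(mat)) mat <- material(mat)
  if (is.character(medium)) medium <- material(medium)
  if (is.null(diameter_mean)) diameter_mean <- mat$nominal_diameter
  if (is.null(stiffness_mean)) stiffness_mean <- mat$nominal_stiffness
  scene_ensemble(function(s) {
    with_seed(s, {
      d <- max(stats::rnorm(1, diameter_mean, diameter_sd),
               0.05 * diameter_mean)
      E <- max(stats::rnorm(1, stiffness_mean, stiffness_sd),
               0.05 * stiffness_mean)
      bead_scene(d, mat, medium, grid_shape, pixel_pitch, stiffness = E)
    })
  }, n, seed)
}

#' Ensemble of jittered cell scenes
#'
#' @param n number of cells
#' @param diameter_mean,diameter_sd per-cell diameter distribution, um
#' @param stiffness_mean,stiffness_sd per-cell mean-stiffness distribution, Pa
#' @param heterogeneity within-cell relative stiffness SD
#' @param grid_shape,pixel_pitch grid geometry
#' @param seed master seed
#' @param ... further arguments passed to \code{\link{cell_scene}}
#' @return list of \code{sample_scene}
#' @export
cell_ensemble <- function(n, diameter_mean = 16, diameter_sd = 1.5,
                          stiffness_mean = 1080, stiffness_sd = 140,
                          heterogeneity = 0.13, grid_shape = c(128, 128),
                          pixel_pitch = 0.18, seed = 1, ...) {
  scene_ensemble(function(s) {
    with_seed(s, {
      d <- max(stats::rnorm(1, diameter_mean, diameter_sd),
               0.3 * diameter_mean)
      E <- max(stats::rnorm(1, stiffness_mean, stiffness_sd),
               0.1 * stiffness_mean)
      cell_scene(mean_diameter = d, base_stiffness = E,
                 heterogeneity = heterogeneity, seed = child_seed(s, 1),
                 grid_shape = grid_shape, pixel_pitch = pixel_pitch, ...)
    })
  }, n, seed)
}
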