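# Shared fixtures, built in code.

# small soft bead (PAA in water) that keeps simulations cheap
small_bead <- function(grid = 48, pitch = 0.12, diameter = 5) {
  bead_scene(diameter, material("PAA"), material("water"),
             grid_shape = c(grid, grid), pixel_pitch = pitch)
}

bead_optics <- function(snr_db = Inf, mean_intensity = 1800) {
  optical_config(wavelength = 0.532, mean_intensity = mean_intensity,
                 visibility = 0.9,
                 noise = noise_for_snr(mean_intensity, snr_db))
}

small_plan <- function(frames = 10, steps = 20) {
  acquisition_plan(n_steps = steps, frames_per_step = frames)
}

# Itoh row/column path-integration unwrapping: the small-instance oracle for
# residue-free wrapped fields (independent of the DCT/PCG solver).
itoh_unwrap <- function(wp) {
  d <- dim(wp)
  out <- matrix(0, d[1], d[2])
  out[, 1] <- cumsum(c(wp[1, 1], wrap_phase(diff(wp[, 1]))))
  for (i in seq_len(d[1])) {
    out[i, ] <- out[i, 1] + cumsum(c(0, wrap_phase(diff(wp[i, ]))))
  }
  out
}

# direct per-pair arithmetic of the determination coefficient, used as the
# oracle against the vectorized matrix implementation
r2_direct <- function(obs, calc) {
  1 - sum((obs - calc)^2) / sum((obs - mean(obs))^2)
}

expect_map_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
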