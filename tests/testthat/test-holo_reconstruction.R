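test_that("injected per-step start offsets are recovered exactly without noise", {
  sc <- small_bead()
  drv <- acoustic_drive(pressure_amplitude = 150)
  for (seed in 1:3) {
    st <- acquire_stack(sc, drv, small_plan(frames = 12), bead_optics(),
                        seed = seed, step_offsets = "random")
    m <- match_step_offset(st)
    truth <- (12 - st$truth$step_offsets) %% 12
    expect_identical(as.integer(m$shifts), as.integer(truth))
  }
  # identical start phases in every step: all shifts zero
  st0 <- acquire_stack(sc, drv, small_plan(frames = 12), bead_optics(),
                       seed = 4, step_offsets = "none")
  expect_true(all(match_step_offset(st0)$shifts == 0))
})

test_that("offset matching is invariant to a global intensity scale", {
  sc <- small_bead()
  st <- acquire_stack(sc, acoustic_drive(pressure_amplitude = 150),
                      small_plan(frames = 12), bead_optics(), seed = 5,
                      step_offsets = "random")
  m1 <- match_step_offset(st)
  st$frames <- lapply(st$frames, function(a) a * 2.7)
  m2 <- match_step_offset(st)
  expect_identical(m1$shifts, m2$shifts)
})

test_that("vibration-free stacks are flagged ambiguous with zero shifts", {
  sc <- small_bead()
  st <- acquire_stack(sc, acoustic_drive(pressure_amplitude = 0),
                      small_plan(frames = 8), bead_optics(), seed = 6)
  expect_warning(m <- match_step_offset(st), "ambiguous")
  expect_true(all(m$shifts == 0))
  expect_true(any(m$ambiguous))
})

test_that("binning is the documented permutation and round-trips", {
  sc <- small_bead()
  st <- acquire_stack(sc, acoustic_drive(pressure_amplitude = 150),
                      small_plan(frames = 6), bead_optics(), seed = 7,
                      step_offsets = c(0, rep(2, 19)))
  shifts <- c(0L, rep(4L, 19L)) # (6 - 2) mod 6
  bs <- bin_frames(st, shifts)
  expect_length(bs$bins, 6)
  expect_equal(dim(bs$bins[[1]])[3], 20)
  expect_equal(bs$psi, 2 * pi * (0:5) / 6)
  # bin j holds frame (j + s_k) mod F of step k
  expect_identical(bs$bins[[2]][, , 3], st$frames[[3]][, , 6])
  # un-binning restores every original frame
  back <- unbin_frames(bs)
  for (k in c(1, 5, 20)) expect_identical(back[[k]], st$frames[[k]])
  expect_error(bin_frames(st, 1:3), "one shift per step")
})

test_that("default full acquisition bins into 50 bins of 20 frames", {
  sc <- bead_scene(5, material("PAA"), grid_shape = c(8, 8),
                   pixel_pitch = 0.9)
  st <- acquire_stack(sc, acoustic_drive(pressure_amplitude = 100),
                      acquisition_plan(), bead_optics(), seed = 8)
  bs <- bin_frames(st)
  expect_length(bs$bins, 50)
  expect_true(all(vapply(bs$bins, function(a) dim(a)[3], numeric(1)) == 20))
})

test_that("least-squares phase retrieval is exact on noiseless fringes", {
  theta <- (0:19) * pi / 10
  phi0 <- 1.000
  frames <- array(0, c(8, 8, 20))
  for (k in 1:20) frames[, , k] <- 900 * (1 + 0.85 * cos(phi0 + theta[k]))
  wp <- retrieve_phase(frames, theta)
  expect_map_equal(wp$phase, matrix(phi0, 8, 8), 1e-9)
  expect_map_equal(wp$amplitude, matrix(900 * 0.85, 8, 8), 1e-6)
  expect_map_equal(wp$visibility, matrix(0.85, 8, 8), 1e-9)
  expect_true(all(wp$quality > 0.999))
  # zero phase: pure cosine component, positive
  for (k in 1:20) frames[, , k] <- 900 * (1 + 0.85 * cos(theta[k]))
  wp0 <- retrieve_phase(frames, theta)
  expect_map_equal(wp0$phase, matrix(0, 8, 8), 1e-9)
})

test_that("phase retrieval is invariant to intensity offset and scale", {
  theta <- (0:19) * pi / 10
  phi <- matrix(seq(-3, 3, length.out = 64), 8, 8)
  frames <- array(0, c(8, 8, 20))
  for (k in 1:20) frames[, , k] <- 700 * (1 + 0.6 * cos(phi + theta[k]))
  base <- retrieve_phase(frames, theta)
  shifted <- retrieve_phase(frames + 123.4, theta)
  scaled <- retrieve_phase(frames * 3.21, theta)
  expect_map_equal(base$phase, shifted$phase, 1e-12)
  expect_map_equal(base$phase, scaled$phase, 1e-12)
  # offsets change only the mean term
  expect_map_equal(base$amplitude, shifted$amplitude, 1e-9)
})

test_that("degenerate phase-step designs are rejected", {
  frames <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_error(retrieve_phase(frames, c(0, 0, 0)), "distinct")
  expect_error(retrieve_phase(frames[, , 1:2, drop = FALSE], c(0, 1)),
               "at least 3")
})

test_that("low-visibility pixels are masked by the quality floor", {
  theta <- (0:9) * 2 * pi / 10
  frames <- array(1000, c(4, 4, 10)) # no fringes at all: visibility 0
  for (k in 1:10) frames[1, 1, k] <- 1000 * (1 + 0.5 * cos(0.3 + theta[k]))
  wp <- retrieve_phase(frames, theta)
  expect_equal(wp$quality[1, 1], 1, tolerance = 1e-6)
  expect_true(all(wp$quality[2:4, ] == 0))
})

test_that("DCT-Poisson unwrapping matches path integration on residue-free fields", {
  g <- seq(-1, 1, length.out = 64)
  phi <- 15 * outer(g^2, g^2, "+") / 2 # smooth quadratic, ~15 rad span
  w <- wrap_phase(phi)
  uw <- unwrap_phase(w)
  expect_s3_class(uw, "unwrapped_phase")
  io <- itoh_unwrap(w)
  dev <- uw$phase - io
  expect_lt(max(abs(dev - dev[1, 1])), 1e-6)
  # wrap-consistency at every pixel
  expect_map_equal(wrap_phase(uw$phase), w, 1e-9)
})

test_that("unwrapping smooth or trivial inputs is the identity up to 2 pi", {
  phi <- matrix(seq(-2, 2, length.out = 256), 16, 16)
  uw <- unwrap_phase(wrap_phase(phi))
  dev <- uw$phase - phi
  expect_lt(diff(range(dev)), 1e-9)       # constant offset only
  expect_equal(dev[1, 1] %% (2 * pi), 0, tolerance = 1e-9)
  z <- unwrap_phase(matrix(0, 12, 12))
  expect_map_equal(z$phase, matrix(0, 12, 12), 1e-12)
  expect_error(unwrap_phase(matrix(c(NA, 1, 2, 3), 2, 2)), "finite")
})

test_that("weighted unwrapping converges through the preconditioned CG path", {
  g <- seq(-1, 1, length.out = 48)
  phi <- 12 * outer(g^2, g^2, "+") / 2
  w <- wrap_phase(phi)
  q <- matrix(1, 48, 48); q[10:20, 10:20] <- 0.3
  uw <- unwrap_phase(w, weights = q)
  expect_lte(uw$residual, 1e-8)
  expect_map_equal(wrap_phase(uw$phase), w, 1e-9)
  io <- itoh_unwrap(w)
  dev <- uw$phase - io
  expect_lt(max(abs(dev - dev[1, 1])), 1e-6)
})

test_that("wrap-consistency holds across random smooth fields", {
  for (s in 1:5) {
    f <- with_seed(s, {
      a <- matrix(stats::rnorm(32 * 32), 32, 32)
      8 * Re(fft(fft(a) * exp(-0.08 * outer((0:31)^2, (0:31)^2, "+")),
                 inverse = TRUE)) / (32 * 32)
    })
    w <- wrap_phase(f)
    uw <- unwrap_phase(w)
    expect_map_equal(wrap_phase(uw$phase), w, 1e-9)
  }
})

test_that("blank subtraction removes a known background aberration", {
  g <- grid_coords(c(32, 32), 1)
  bg <- 0.4 + 0.05 * outer(g$y, rep(1, 32)) +
    0.002 * outer(g$y^2, rep(1, 32)) + 0.03 * outer(rep(1, 32), g$x)
  phi <- matrix(0.7, 32, 32)
  u_sample <- unwrap_phase(wrap_phase(phi + bg))
  u_blank <- unwrap_phase(wrap_phase(bg))
  diffm <- reference_subtract(u_sample, u_blank)
  # the sample phase is flat, so after anchoring the residual is ~0
  expect_lt(max(abs(diffm$phase - median(diffm$phase))), 1e-6)
  expect_map_equal(reference_subtract(u_sample, u_sample)$phase,
                   matrix(0, 32, 32), 1e-12)
  expect_error(reference_subtract(u_sample, matrix(0, 8, 8)), "shapes")
})

test_that("phase converts to thickness by the optical-path relation", {
  # full fringe of PS in water: lambda / delta_n
  expect_equal(phase_to_thickness(2 * pi, 0.532, 1.5915, 1.334),
               0.532 / 0.2575, tolerance = 1e-12)
  expect_equal(phase_to_thickness(2 * pi, 0.532, 1.5915, 1.334), 2.0660,
               tolerance = 1e-4)
  expect_equal(phase_to_thickness(0, 0.532, 1.5915, 1.334), 0)
  # doubling the contrast halves the thickness
  h1 <- phase_to_thickness(3, 0.527, 1.375, 1.337)
  h2 <- phase_to_thickness(3, 0.527, 1.413, 1.337)
  expect_equal(h1 / h2, 2, tolerance = 1e-12)
  expect_error(phase_to_thickness(1, 0.532, 1.334, 1.334), "contrast")
})

test_that("the collaborative filter denoises without touching clean input", {
  x <- outer(1:48, 1:48, function(i, j) 1000 + 800 * cos(0.3 * i + 0.2 * j))
  xn <- with_seed(21, x + matrix(stats::rnorm(48 * 48, 0, 10), 48, 48))
  expect_identical(denoise_frame(xn, 0), xn)
  dn <- denoise_frame(xn, 10)
  expect_lt(sqrt(mean((dn - x)^2)), sqrt(mean((xn - x)^2)))
  # flat image: output variance strictly below input variance
  flat <- with_seed(22, matrix(stats::rnorm(40 * 40, 500, 8), 40, 40))
  expect_lt(var(as.vector(denoise_frame(flat, 8))), var(as.vector(flat)))
  expect_error(denoise_frame(flat, -1), "non-negative")
})
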