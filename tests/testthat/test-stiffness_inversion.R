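make_disp <- function(delta, h0, resid = 0, pitch = 1) {
  d <- dim(delta)
  out <- list(amplitude = delta, phase = matrix(0, d[1], d[2]),
              h0_est = h0, residual = matrix(resid, d[1], d[2]),
              valid = h0 > 0 & delta < pmax(h0, .Machine$double.eps),
              pixel_pitch = pitch)
  class(out) <- "displacement_map"
  out
}

test_that("displacement fit recovers amplitude and rest thickness exactly", {
  psi <- 2 * pi * (0:49) / 50
  maps <- lapply(psi, function(p) matrix(3 - 0.1 * (1 + sin(p)) / 2, 6, 6))
  fd <- fit_displacement(list(maps = maps, psi = psi, pixel_pitch = 0.1))
  expect_map_equal(fd$amplitude, matrix(0.1, 6, 6), 1e-12)
  expect_map_equal(fd$h0_est, matrix(3, 6, 6), 1e-12)
  expect_true(all(fd$valid))
  # constant series: zero amplitude
  flat <- lapply(psi, function(p) matrix(2, 6, 6))
  fd0 <- fit_displacement(list(maps = flat, psi = psi, pixel_pitch = 0.1))
  expect_map_equal(fd0$amplitude, matrix(0, 6, 6), 1e-12)
  # amplitude invariant under cyclic bin relabeling
  rot <- c(8:50, 1:7)
  fdr <- fit_displacement(list(maps = maps[rot], psi = psi,
                               pixel_pitch = 0.1))
  expect_map_equal(fdr$amplitude, fd$amplitude, 1e-12)
  expect_error(fit_displacement(list(maps = maps[1:2], psi = psi[1:2])),
               "at least 3")
})

test_that("the local elastic column gives the closed-form deflection", {
  E <- matrix(1940, 8, 8)
  h0 <- matrix(31, 8, 8)
  p <- elastic_params(poisson_ratio = 0.5, p0 = 10)
  w <- elastic_forward(E, h0, p)
  expect_map_equal(w, matrix(10 * 31 * 0.75 / 1940, 8, 8), 1e-12)
  expect_equal(w[1, 1], 0.1198, tolerance = 1e-3)
  # infinitely stiff: no deflection
  wInf <- elastic_forward(matrix(1e15, 8, 8), h0, p)
  expect_lt(max(wInf), 1e-9)
  E2 <- E; E2[3, 3] <- 0
  expect_error(elastic_forward(E2, h0, p), "\\(3, 3\\)")
})

test_that("membrane coupling matches an independent dense solve", {
  # oracle: assemble the coupled-spring/membrane system densely from the
  # PDE and solve with base R
  n <- 24
  g <- grid_coords(c(n, n), 1)
  r <- sqrt(outer(g$y^2, g$x^2, "+"))
  h0 <- matrix(0, n, n); h0[r < 9] <- 6 * (1 - (r[r < 9] / 9)^2)
  E <- matrix(1500, n, n) + 400 * outer(sin(seq_len(n) / 3), cos(seq_len(n) / 4))
  p <- elastic_params(poisson_ratio = 0.5, lateral_coupling = 1e-4, p0 = 20)
  w <- elastic_forward(E, h0, p, pixel_pitch = 0.5)
  mask <- h0 > 0
  idx <- which(mask)
  np <- length(idx)
  A <- matrix(0, np, np)
  Tpa <- 1e-4 * 1e6 # N/m in Pa*um
  ip2 <- 1 / 0.5^2
  pos <- matrix(NA_integer_, n, n); pos[idx] <- seq_len(np)
  for (q in seq_len(np)) {
    i <- (idx[q] - 1) %% n + 1; j <- (idx[q] - 1) %/% n + 1
    A[q, q] <- E[i, j] / (0.75 * h0[i, j]) + 4 * Tpa * ip2
    for (s in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (s[1] >= 1 && s[1] <= n && s[2] >= 1 && s[2] <= n &&
          !is.na(pos[s[1], s[2]])) {
        A[q, pos[s[1], s[2]]] <- -Tpa * ip2
      }
    }
  }
  w_dense <- rep(0, np)
  w_dense <- solve(A, rep(20, np))
  expect_lt(max(abs(w[idx] - w_dense)) / max(abs(w_dense)), 1e-8)
})

test_that("stiffness inversion is the exact algebraic inverse when T = 0", {
  sc <- small_bead()
  p <- elastic_params(p0 = 120)
  w <- elastic_forward(sc$E_true, sc$h0, p)
  disp <- make_disp(w, sc$h0)
  sm <- invert_stiffness(disp, p)
  expect_map_equal(sm$E[sm$mask], sc$E_true[sm$mask], 1e-9)
  expect_equal(sm$summary$n_pixels, sum(sm$mask))
  expect_equal(sm$summary$mean, mean(sm$E[sm$mask]))
  # zero-displacement pixels stay out of the mask
  expect_true(all(disp$amplitude[!sm$mask] <= 0 | sc$h0[!sm$mask] <= 0))
})

test_that("iterative inversion recovers a smooth heterogeneous field with T > 0", {
  n <- 32
  g <- grid_coords(c(n, n), 1)
  r <- sqrt(outer(g$y^2, g$x^2, "+"))
  h0 <- matrix(0, n, n); h0[r < 12] <- 5 * (1 - (r[r < 12] / 12)^2) + 1
  h0[r >= 12] <- 0
  E <- matrix(1200, n, n) * (1 + 0.3 * outer(sin(seq_len(n) / 5),
                                             cos(seq_len(n) / 6)))
  p <- elastic_params(lateral_coupling = 5e-5, p0 = 15, tol = 1e-10,
                      max_iter = 200)
  w <- elastic_forward(E, h0, p, pixel_pitch = 1)
  disp <- make_disp(w, h0)
  sm <- invert_stiffness(disp, p, pixel_pitch = 1)
  rel <- abs(sm$E[sm$mask] - E[sm$mask]) / E[sm$mask]
  expect_lt(max(rel), 0.01)
})

test_that("recovered stiffness is monotone in displacement and scales with p0", {
  h0 <- matrix(4, 5, 5)
  deltas <- matrix(seq(0.05, 0.4, length.out = 25), 5, 5)
  p <- elastic_params(p0 = 50)
  sm <- invert_stiffness(make_disp(deltas, h0), p)
  ord <- order(as.vector(deltas))
  expect_true(all(diff(as.vector(sm$E)[ord]) < 0))
  sm2 <- invert_stiffness(make_disp(deltas, h0),
                          elastic_params(p0 = 150))
  expect_map_equal(sm2$E / sm$E, matrix(3, 5, 5), 1e-12)
})

test_that("pressure calibration closes on a known reference", {
  sc <- small_bead()
  p <- elastic_params(p0 = 10)
  w <- elastic_forward(sc$E_true, sc$h0, p)
  disp <- make_disp(w, sc$h0)
  cal <- calibrate_pressure(disp, E_ref = 1940)
  expect_equal(cal$p0, 10, tolerance = 1e-3 * 0.1)
  expect_lt(cal$dispersion, 1e-12)
  # doubling the reference stiffness doubles the recovered pressure
  cal2 <- calibrate_pressure(disp, E_ref = 2 * 1940)
  expect_equal(cal2$p0 / cal$p0, 2, tolerance = 1e-12)
  empty <- make_disp(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_error(calibrate_pressure(empty, 1000), "empty")
})

test_that("inversion refuses unset pressure and all-masked input", {
  disp <- make_disp(matrix(0.1, 4, 4), matrix(2, 4, 4))
  expect_error(invert_stiffness(disp, elastic_params()), "p0")
  none <- make_disp(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_error(invert_stiffness(none, elastic_params(p0 = 10)), "masked")
})
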