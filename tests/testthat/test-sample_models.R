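test_that("material table carries the reference presets with valid optics", {
  tab <- material_table()
  expect_setequal(
    c("PS", "PAA", "agarose", "water", "DMEM/F12", "glycerol"),
    intersect(tab$name, c("PS", "PAA", "agarose", "water", "DMEM/F12",
                          "glycerol")))
  expect_true(all(tab$refractive_index > 1))
  expect_true(all(is.na(tab$nominal_stiffness) | tab$nominal_stiffness > 0))
  # index contrast of PS in water drives the strongest fringes
  expect_equal(material("PS")$refractive_index -
                 material("water")$refractive_index, 0.2575)
  expect_error(material("unobtainium"), "unknown material")
})

test_that("bead thickness equals the projected chord of a sphere", {
  sc <- bead_scene(5, grid_shape = c(64, 64), pixel_pitch = 0.1)
  g <- expand.grid(y = (1:64 - 32.5) * 0.1, x = (1:64 - 32.5) * 0.1)
  r2 <- g$y^2 + g$x^2
  expected <- ifelse(r2 < 2.5^2, 2 * sqrt(pmax(2.5^2 - r2, 0)), 0)
  expect_map_equal(as.vector(sc$h0), expected, 1e-9)
  # central chord equals the diameter (grid point nearest the center)
  expect_lt(abs(max(sc$h0) - 5), 5e-3)
  # outside the support the thickness vanishes
  expect_true(all(sc$h0[r2 >= 2.5^2] == 0))
  # hand-worked value at r = 1.25 um
  sc2 <- bead_scene(5, grid_shape = c(41, 41), pixel_pitch = 0.125)
  # pixel (21, 31) sits exactly at (0, 1.25) um from the center
  expect_equal(sc2$h0[21, 31], 2 * sqrt(2.5^2 - 1.25^2), tolerance = 1e-12)
  expect_equal(sc2$h0[21, 31], 4.330127, tolerance = 1e-6)
})

test_that("oversized beads and invalid materials are rejected", {
  expect_error(bead_scene(10, grid_shape = c(32, 32), pixel_pitch = 0.1),
               "does not fit")
  expect_error(bead_scene(-1), "positive")
  expect_error(bead_scene(5, material("water")), "stiffness")
})

test_that("cell scenes are reproducible, heterogeneity-controlled blobs", {
  a <- cell_scene(seed = 7, grid_shape = c(48, 48), pixel_pitch = 0.5)
  b <- cell_scene(seed = 7, grid_shape = c(48, 48), pixel_pitch = 0.5)
  expect_identical(a, b)
  c2 <- cell_scene(seed = 8, grid_shape = c(48, 48), pixel_pitch = 0.5)
  expect_false(isTRUE(all.equal(a$h0, c2$h0)))
  # zero heterogeneity: stiffness constant on the support
  h0 <- cell_scene(heterogeneity = 0, seed = 3, grid_shape = c(48, 48),
                   pixel_pitch = 0.5, base_stiffness = 1080)
  expect_true(all(h0$E_true[h0$support] == 1080))
  expect_error(cell_scene(grid_shape = c(4, 4)), "degenerate")
  expect_error(cell_scene(mean_thickness = -1), "positive")
  expect_error(cell_scene(heterogeneity = 1.2), "heterogeneity")
})

test_that("every generated scene satisfies support and positivity invariants", {
  for (s in 1:1000) {
    sc <- if (s %% 2) {
      cell_scene(seed = s, grid_shape = c(24, 24), pixel_pitch = 1)
    } else {
      with_seed(s, bead_scene(stats::runif(1, 1, 8), material("PAA"),
                              grid_shape = c(24, 24), pixel_pitch = 0.5))
    }
    expect_true(all(sc$h0 >= 0))
    expect_identical(sc$h0 > 0, sc$support)
    expect_true(all(sc$E_true[sc$support] > 0))
  }
})

test_that("ensembles derive reproducible child scenes with configured jitter", {
  ens <- bead_ensemble(50, diameter_mean = 5, diameter_sd = 0.3, stiffness_sd = 100, seed = 5,
                       grid_shape = c(24, 24), pixel_pitch = 0.5,
                       mat = material("PAA"))
  expect_length(ens, 50)
  # n = 1 equals the direct factory call with the first child seed
  one <- bead_ensemble(1, diameter_mean = 5, diameter_sd = 0.3, stiffness_sd = 100, seed = 5,
                       grid_shape = c(24, 24), pixel_pitch = 0.5,
                       mat = material("PAA"))
  expect_identical(one[[1]], ens[[1]])
  # zero jitter: identical geometry across the ensemble
  flat <- bead_ensemble(5, diameter_mean = 5, diameter_sd = 0, stiffness_sd = 0, seed = 5,
                        grid_shape = c(24, 24), pixel_pitch = 0.5,
                        mat = material("PAA"))
  for (k in 2:5) expect_identical(flat[[k]]$h0, flat[[1]]$h0)
  expect_error(scene_ensemble(function(s) small_bead(), 0), "at least 1")
})

test_that("generator moments converge to the configured distributions", {
  # bead jitter moments at n = 10000 within 3 standard errors
  n <- 10000
  mu_d <- 31; sd_d <- 2; mu_E <- 1940; sd_E <- 170
  ds <- numeric(n); Es <- numeric(n)
  for (i in seq_len(n)) {
    s <- child_seed(42, i)
    with_seed(s, {
      ds[i] <- max(stats::rnorm(1, mu_d, sd_d), 0.05 * mu_d)
      Es[i] <- max(stats::rnorm(1, mu_E, sd_E), 0.05 * mu_E)
    })
  }
  expect_lt(abs(mean(ds) - mu_d), 3 * sd_d / sqrt(n))
  expect_lt(abs(mean(Es) - mu_E), 3 * sd_E / sqrt(n))
  expect_lt(abs(sd(ds) - sd_d), 3 * sd_d / sqrt(n))
  # ensemble mean of per-scene mean stiffness: log-normal field calibrated
  # so the spatial mean matches the configured base value within 2%
  m <- numeric(10000)
  for (i in seq_along(m)) {
    sc <- cell_scene(base_stiffness = 1080, heterogeneity = 0.13,
                     seed = child_seed(9, i), grid_shape = c(32, 32),
                     pixel_pitch = 0.6)
    m[i] <- mean(sc$E_true[sc$support])
  }
  expect_lt(abs(mean(m) - 1080) / 1080, 0.02)
})
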