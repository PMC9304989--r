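test_that("probe geometry places fibers at equal angles on the ring", {
  probe <- make_probe(4L, 9, 2L)
  expect_equal(probe$fiber_angles, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(sqrt(probe$fiber_x^2 + probe$fiber_y^2), rep(9, 4))

  default <- make_probe()
  expect_equal(default$n_fibers, 12L)
  expect_equal(default$sd_separation, 9)
  expect_equal(default$pixels_per_fiber, 8L)
  expect_equal(diff(default$fiber_angles), rep(pi / 6, 11))

  expect_error(make_probe(0), "positive integer")
  expect_error(make_probe(12, -1), "positive")
  expect_error(make_probe(12, 9, 2.5), "positive integer")
})

test_that("tissue presets carry the documented optics and baseline decay", {
  t1 <- tissue_preset("tissue1")
  t2 <- tissue_preset("tissue2")
  expect_equal(t1$mu_s_prime, 0.7)
  expect_equal(t1$mu_a, 0.01)
  expect_equal(t2$mu_s_prime, 1.2)
  expect_equal(t2$mu_a, 0.02)
  # baseline decorrelation time scales inversely with reduced scattering
  expect_equal(t1$tau_c_baseline, 1e-3)
  expect_equal(t2$tau_c_baseline, 1e-3 * 0.7 / 1.2)
  expect_error(tissue_preset("tissue3"))
})

test_that("CW diffuse reflectance decreases with distance and absorption", {
  r <- cw_reflectance(c(5, 9, 15), 0.01, 0.7)
  expect_true(all(r > 0))
  expect_true(all(diff(r) < 0))
  expect_lt(cw_reflectance(9, 0.02, 0.7), cw_reflectance(9, 0.01, 0.7))
  # the more turbid preset detects fewer photons at the fixed separation
  expect_lt(cw_reflectance(9, 0.02, 1.2), cw_reflectance(9, 0.01, 0.7))
})

test_that("simulation config fixes the bin width by sensor scale", {
  expect_equal(sim_config()$dt, 1e-5)
  expect_equal(sim_config(scale = "full")$dt, 1.5e-6)
  expect_error(sim_config(beta = 0), "beta")
  expect_error(sim_config(beta = 1.5), "beta")
  expect_error(sim_config(mean_rate = -1), "positive")
})

test_that("sensor layout maps every fiber to its pixel block", {
  probe <- make_probe()
  layout <- make_sensor_layout(probe)
  expect_equal(layout$nx, 10L)
  expect_equal(layout$ny, 12L)
  expect_equal(layout$n_pixels, 120L)
  counts <- tabulate(layout$pixel_to_fiber, nbins = 12L)
  expect_equal(counts, rep(8L, 12L))
  expect_equal(sum(is.na(layout$pixel_to_fiber)), 24L)
  # centroids are the mean coordinates of each block's pixels
  for (p in c(1L, 7L, 12L)) {
    px <- which(layout$pixel_to_fiber == p)
    expect_equal(colMeans(layout$pixel_xy[px, , drop = FALSE]),
                 c(x = layout$centroids[p, 1], y = layout$centroids[p, 2]))
  }
  full <- make_sensor_layout(probe, "full")
  expect_equal(c(full$nx, full$ny), c(32L, 32L))
  expect_equal(tabulate(full$pixel_to_fiber, nbins = 12L), rep(8L, 12L))
})
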