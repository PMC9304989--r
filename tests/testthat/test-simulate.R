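test_that("simulated events are integer count frames with the right shape", {
  ev <- fixture_event()
  expect_s3_class(ev, "photon_frame_series")
  expect_equal(dim(ev$counts), c(5000L, 120L))
  expect_true(is.integer(ev$counts))
  expect_true(all(ev$counts >= 0))
  expect_equal(ev$dt, 1e-5)
  expect_equal(ev$duration, 0.05)
  expect_equal(attr(ev, "tau_p"), rep(1e-3, 12))
})

test_that("event simulation is deterministic in the seed", {
  pat <- tubes_pattern(c(0.7, 1.4))
  probe <- make_probe()
  t2 <- tissue_preset("tissue2")
  cfg <- sim_config()
  a <- simulate_event(pat, probe, t2, cfg, duration = 0.01, seed = 5)
  b <- simulate_event(pat, probe, t2, cfg, duration = 0.01, seed = 5)
  d <- simulate_event(pat, probe, t2, cfg, duration = 0.01, seed = 6)
  expect_identical(a$counts, b$counts)
  expect_gt(sum(a$counts != d$counts), 0)
})

test_that("count rates follow the configured photon budget", {
  ev <- fixture_event() # tissue1 reference, mean_rate 0.03, dark 5e-4
  mapped <- !is.na(ev$layout$pixel_to_fiber)
  m_on <- mean(ev$counts[, mapped])
  m_off <- mean(ev$counts[, !mapped])
  expect_gt(m_on, 0.03 * 0.85)
  expect_lt(m_on, 0.03 * 1.15)
  expect_gt(m_off, 5e-4 * 0.4)
  expect_lt(m_off, 5e-4 * 2.5)

  # the more turbid preset is photon starved via its reflectance ratio
  pat <- tubes_pattern(c(0, 0))
  ev2 <- simulate_event(pat, make_probe(), tissue_preset("tissue2"),
                        sim_config(seed = 42L), duration = 0.05)
  mapped2 <- !is.na(ev2$layout$pixel_to_fiber)
  ratio <- cw_reflectance(9, 0.02, 1.2) / cw_reflectance(9, 0.01, 0.7)
  expect_equal(mean(ev2$counts[, mapped2]) / 0.03, ratio, tolerance = 0.15)
})

test_that("photon sampling preserves the target mean rate", {
  x <- sample_photon_counts(rep(2.5, 20000), mean_rate = 0.2, seed = 3)
  expect_true(is.integer(x))
  expect_equal(mean(x), 0.2, tolerance = 0.05)
  expect_identical(x, sample_photon_counts(rep(2.5, 20000), 0.2, seed = 3))
  expect_error(sample_photon_counts(c(-1, 1), 0.2, 1), "non-negative")
})

test_that("circulant field synthesis reproduces the target correlation", {
  g1f <- function(tau) field_g1(tau, "exponential", list(tau_c = 1e-3))
  E <- simulate_field_trace(g1f, 40000L, 1e-5, seed = 11)
  expect_length(E, 40000L)
  expect_equal(mean(Mod(E)^2), 1, tolerance = 0.2)
  lag <- 100L
  n <- length(E)
  emp <- Mod(sum(Conj(E[1:(n - lag)]) * E[(1 + lag):n])) /
    sum(Mod(E)^2) * n / (n - lag)
  expect_equal(emp, exp(-1), tolerance = 0.15)
})

test_that("non-exponential field models drive the per-pixel path", {
  pat <- tubes_pattern(c(1, 1))
  ev <- simulate_event(pat, make_probe(), tissue_preset("tissue2"),
                       sim_config(seed = 9L, g1_model = "semi_infinite_cde"),
                       duration = 0.005)
  expect_equal(dim(ev$counts), c(500L, 120L))
  expect_true(all(ev$counts >= 0))
  ev2 <- simulate_event(pat, make_probe(), tissue_preset("tissue2"),
                        sim_config(seed = 9L, g1_model = "semi_infinite_cde"),
                        duration = 0.005)
  expect_identical(ev$counts, ev2$counts)
})
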