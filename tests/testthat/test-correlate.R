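test_that("lag grids start at one bin and respect the window bound", {
  g <- lag_grid(1e-5, 0.2, tau_expected = 1e-3)
  expect_s3_class(g, "lag_grid")
  expect_equal(g$bins[1], 1L)
  expect_true(all(diff(g$bins) > 0))
  expect_lte(max(g$bins) * 1e-5, 5e-3)
  expect_equal(g$lags_s, g$bins * 1e-5)
  # the T_int / 10 cap binds for short windows
  g2 <- lag_grid(1e-5, 0.01, tau_expected = 1e-3)
  expect_lte(max(g2$bins) * 1e-5, 1e-3 + 1e-12)
  expect_error(lag_grid(-1, 0.1), "positive")
})

test_that("per-pixel autocorrelation matches the direct-sum oracle", {
  ev <- fixture_event()
  grid <- lag_grid(ev$dt, ev$duration, tau_expected = 1e-3)
  px <- c(1L, 13L, 60L, 120L)
  for (norm in c("symmetric", "whole_window")) {
    got <- pixel_autocorrelation(ev$counts[, px], grid, normalization = norm)
    expect_s3_class(got, "g2_curve")
    for (j in seq_along(px)) {
      want <- oracle_g2(ev$counts[, px[j]], grid$bins,
                        symmetric = (norm == "symmetric"))
      expect_equal(unname(unclass(got)[, j]), want, tolerance = 1e-12)
    }
  }
})

test_that("empty windows flag undefined correlations instead of failing", {
  zeros <- matrix(0L, 1000L, 2L)
  grid <- lag_grid(1e-5, 0.01, tau_expected = 1e-3)
  g2 <- pixel_autocorrelation(zeros, grid)
  expect_true(all(is.na(unclass(g2))))
})

test_that("uncorrelated shot noise gives a flat correlation near one", {
  counts <- matrix(speckleclass:::with_seed(314,
    stats::rpois(20000L * 4L, 1.0)), 20000L, 4L)
  storage.mode(counts) <- "integer"
  grid <- lag_grid(1e-5, 0.2, tau_expected = 1e-3)
  g2 <- rowMeans(unclass(pixel_autocorrelation(counts, grid)))
  expect_true(all(abs(g2 - 1) < 0.05))
})

test_that("flat-field lookup table recovers the true pixel mapping", {
  probe <- make_probe()
  layout <- make_sensor_layout(probe)
  mean_image <- ifelse(is.na(layout$pixel_to_fiber), 0.01, 1.0)
  lut <- build_lookup_table(mean_image, probe, layout = layout)
  expect_identical(lut$pixel_to_fiber, layout$pixel_to_fiber)
  expect_equal(lut$Q_p, rep(8L, 12L))
  expect_identical(lookup_from_layout(layout)$pixel_to_fiber,
                   layout$pixel_to_fiber)
  expect_error(build_lookup_table(mean_image, probe, threshold_fraction = 1.5,
                                  layout = layout), "threshold")
  expect_error(build_lookup_table(mean_image[-1], probe, layout = layout),
               "length")
})

test_that("fiber averaging pools pixels and skips undefined entries", {
  ev <- fixture_event()
  grid <- lag_grid(ev$dt, ev$duration, tau_expected = 1e-3)
  px <- pixel_autocorrelation(ev$counts, grid)
  lut <- lookup_from_layout(ev$layout)
  f1 <- fiber_average(px, lut, 1L)
  idx <- which(lut$pixel_to_fiber == 1L)
  expect_equal(as.numeric(f1),
               rowMeans(unclass(px)[, idx, drop = FALSE], na.rm = TRUE))
  expect_equal(unname(attr(f1, "n_eff")),
               rowSums(!is.na(unclass(px)[, idx, drop = FALSE])))
  expect_error(fiber_average(px, list(pixel_to_fiber = rep(NA, 120)), 1),
               "no mapped pixels")

  curves <- event_fiber_curves(ev, grid)
  expect_equal(dim(curves), c(length(grid$bins), 12L))
  expect_equal(curves[, 1], as.numeric(f1))
})

test_that("windowing and feature assembly give fiber-major rows", {
  ev <- fixture_event()
  w <- window_event(ev, 0.02)
  expect_equal(nrow(w$counts), 2000L)
  expect_identical(w$counts, ev$counts[1:2000, ])
  expect_error(window_event(ev, 1), "exceeds")

  events <- list(
    list(event_id = 1, class_label = 1L, series = ev),
    list(event_id = 2, class_label = 2L, series = ev))
  grid <- lag_grid(ev$dt, 0.02, tau_expected = 1e-3)
  fx <- assemble_features(events, grid, t_int = 0.02)
  L <- length(grid$bins)
  expect_equal(dim(fx$features), c(2L, 12L * L))
  expect_equal(fx$labels, c(1L, 2L))
  # fiber-major flattening: first L columns are fiber 1's curve
  curves <- event_fiber_curves(ev, grid, t_int = 0.02)
  raw <- assemble_features(events, grid, t_int = 0.02,
                           normalization = "none")
  expect_equal(unname(raw$features[1, 1:L]), unname(curves[, 1]))
  # excess normalization: mean first-lag excess across fibers equals one
  zl <- seq(1, ncol(fx$features), by = L)
  expect_equal(unname(rowMeans(fx$features[, zl])), c(1, 1))
})
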