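test_that("panel grid and sensitivity kernel are well formed", {
  grid <- panel_grid()
  expect_equal(length(grid$x), 32L * 42L)
  expect_equal(range(grid$x), c(-5.3, 5.3))
  expect_equal(range(grid$y), c(-6.95, 6.95))

  probe <- make_probe()
  K <- sensitivity_kernel(probe, grid)
  expect_equal(dim(K), c(length(grid$x), 12L))
  expect_true(all(K >= 0))
  expect_equal(colSums(K), rep(1, 12))
  # each fiber's weight field peaks at the cell nearest the fiber
  for (p in c(1L, 5L)) {
    top <- which.max(K[, p])
    d <- sqrt((grid$x - probe$fiber_x[p])^2 + (grid$y - probe$fiber_y[p])^2)
    expect_lte(d[top], min(d) + 0.5)
  }
})

test_that("letter patterns rasterize distinct glyphs", {
  grid <- panel_grid()
  masks <- lapply(c("D", "U", "K", "E"), letter_pattern, grid = grid)
  for (m in masks) {
    expect_s3_class(m, "perturbation_pattern")
    expect_gt(sum(m$mask), 0)
    expect_true(all(m$mask %in% c(0, 1)))
  }
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(sum(masks[[i]]$mask != masks[[j]]$mask), 0)
  expect_equal(vapply(masks, `[[`, integer(1), "class_label"), 1:4)
  expect_error(letter_pattern("Z"))
  # affine jitter moves the glyph without destroying it
  shifted <- letter_pattern("D", grid, shift = c(0.5, -0.5), rot = 0.1,
                            scale = 1.05)
  expect_gt(sum(shifted$mask), 0)
  expect_gt(sum(shifted$mask != masks[[1]]$mask), 0)
})

test_that("circle classes cross size with flip rate", {
  grid <- panel_grid()
  p <- lapply(1:4, circles_pattern, grid = grid)
  # classes 1/2 small, 3/4 large; classes 1/3 slow, 2/4 fast
  expect_equal(sum(p[[1]]$mask), sum(p[[2]]$mask))
  expect_gt(sum(p[[3]]$mask), sum(p[[1]]$mask))
  expect_equal(vapply(p, `[[`, numeric(1), "flip_rate"),
               c(5000, 10000, 5000, 10000))
  expect_equal(p[[2]]$rate_scale, 2 * p[[1]]$rate_scale)
  expect_error(circles_pattern(5))
})

test_that("tube patterns encode flow speed and depth attenuation", {
  grid <- panel_grid()
  still <- tubes_pattern(c(0, 0), grid)
  expect_true(all(still$mask == 0))
  flowing <- tubes_pattern(c(0.7, 1.4), grid)
  expect_true(any(flowing$mask > 0))
  # left tube at half the right tube's relative speed
  left <- grid$x < 0 & flowing$mask > 0
  right <- grid$x > 0 & flowing$mask > 0
  expect_equal(unique(flowing$mask[left]), 0.7 / 2)
  expect_equal(unique(flowing$mask[right]), 1.4 / 2)
  # deeper tubes couple more weakly
  deep <- tubes_pattern(c(1, 1), grid, depth = 8)
  shallow <- tubes_pattern(c(1, 1), grid, depth = 5)
  expect_lt(deep$rate_scale, shallow$rate_scale)
  expect_equal(deep$rate_scale / shallow$rate_scale, exp(-3 / 1.5))
})

test_that("perturbations shorten fiber decorrelation times coherently", {
  grid <- panel_grid()
  probe <- make_probe()
  K <- sensitivity_kernel(probe, grid)
  t1 <- tissue_preset("tissue1")
  t2 <- tissue_preset("tissue2")

  still <- tubes_pattern(c(0, 0), grid)
  expect_equal(pattern_to_fiber_tau(still, K, t1),
               rep(t1$tau_c_baseline, 12))

  pat <- letter_pattern("E", grid)
  tau <- pattern_to_fiber_tau(pat, K, t1)
  expect_true(all(tau > 0 & tau < t1$tau_c_baseline))
  # doubling the perturbation rate shortens every tau further
  tau2 <- pattern_to_fiber_tau(pat, K, t1, rate_scale = 2 * pat$rate_scale)
  expect_true(all(tau2 < tau))
  # higher turbidity weakens the relative perturbation
  taut2 <- pattern_to_fiber_tau(pat, K, t2)
  expect_true(all(taut2 / t2$tau_c_baseline > tau / t1$tau_c_baseline))
  expect_error(pattern_to_fiber_tau(pat, K[-1, ], t1), "grids")
})
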