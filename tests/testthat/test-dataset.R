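test_that("experiment specs encode the benchmark defaults", {
  s <- experiment_spec("letters_DUKE")
  expect_equal(s$per_class, 200L)
  expect_equal(s$K, 4L)
  expect_equal(s$tissue, "tissue1")
  expect_equal(s$t_int, c(0.2, 0.4))
  s9 <- experiment_spec("tubes_9combo")
  expect_equal(s9$per_class, 100L)
  expect_equal(s9$K, 9L)
  expect_equal(s9$tissue, "tissue2")
  sd3 <- experiment_spec("tubes_depth", depth = 7)
  expect_equal(sd3$K, 3L)
  expect_equal(sd3$depth, 7)
  expect_error(experiment_spec("nonsense"))
})

test_that("dataset plans are balanced, shuffled and reproducible", {
  spec <- experiment_spec("letters_DUKE", per_class = 10, seed = 3)
  plan <- dataset_plan(spec)
  expect_equal(nrow(plan), 40L)
  expect_equal(as.integer(table(plan$class_label)), rep(10L, 4L))
  expect_false(all(plan$class_label == rep(1:4, each = 10))) # shuffled
  expect_identical(plan, dataset_plan(spec))
  expect_false(identical(plan$class_label,
                         dataset_plan(spec, seed = 4)$class_label))
  expect_equal(length(unique(plan$event_seed)), 40L)
  # letter nuisances within the declared jitter ranges
  expect_true(all(abs(plan$shift_x) <= 0.5 & abs(plan$shift_y) <= 0.5))
  expect_true(all(abs(plan$rot) <= 0.15))
  expect_true(all(plan$scale >= 0.9 & plan$scale <= 1.1))
})

test_that("tube plans assign the factorial flow states with pump jitter", {
  spec <- experiment_spec("tubes_9combo", per_class = 6, seed = 2)
  plan <- dataset_plan(spec)
  states <- c(0, 0.7, 1.4)
  nominal_a <- states[(plan$class_label - 1L) %/% 3L + 1L]
  nominal_b <- states[(plan$class_label - 1L) %% 3L + 1L]
  expect_true(all((nominal_a == 0) == (plan$flow_a == 0)))
  expect_true(all((nominal_b == 0) == (plan$flow_b == 0)))
  on_a <- nominal_a > 0
  expect_true(all(abs(log(plan$flow_a[on_a] / nominal_a[on_a])) < 0.2))
})

test_that("generated datasets carry labeled photon records", {
  spec <- experiment_spec("circles", per_class = 2, t_int = 0.02, seed = 6)
  ds <- generate_dataset(spec)
  expect_s3_class(ds, "decorrelation_dataset")
  expect_length(ds$events, 8L)
  labs <- vapply(ds$events, `[[`, integer(1), "class_label")
  expect_equal(sort(as.integer(table(labs))), rep(2L, 4L))
  ev <- ds$events[[1]]
  expect_s3_class(ev$series, "photon_frame_series")
  expect_equal(nrow(ev$series$counts), 2000L)
  expect_length(ev$tau_p, 12L)
  # regenerating with the same seed reproduces every record
  ds2 <- generate_dataset(spec)
  expect_identical(ds$events[[3]]$series$counts,
                   ds2$events[[3]]$series$counts)
})
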