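test_that("the experiment runner produces a consolidated accuracy table", {
  spec <- experiment_spec("circles", per_class = 3, t_int = 0.05, seed = 8)
  res <- run_experiment(spec, methods = "pca")
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$report), 1L)
  expect_equal(res$report$method, "pca")
  expect_equal(res$report$n_events, 12L)
  expect_gte(res$report$accuracy, 0)
  expect_lte(res$report$accuracy, 1)
  expect_output(print(res), "two decimals")
})

test_that("streamed features match retained-dataset assembly exactly", {
  spec <- experiment_spec("tubes_depth", per_class = 2,
                          t_int = c(0.02, 0.04), seed = 13)
  streamed <- stream_features(spec)
  expect_named(streamed, c("0.02", "0.04"))
  ds <- generate_dataset(spec)
  for (ti in spec$t_int) {
    grid <- lag_grid(1e-5, ti,
                     tau_expected = tissue_preset(spec$tissue)$tau_c_baseline)
    fx <- assemble_features(ds, grid, t_int = ti)
    st <- streamed[[as.character(ti)]]
    expect_identical(st$features, fx$features)
    expect_identical(st$labels, fx$labels)
    expect_equal(st$event_ids, fx$event_ids)
  }
})

test_that("datasets round-trip through the directory container", {
  dir <- file.path(tempdir(), "sc-ds-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  spec <- experiment_spec("tubes_depth", per_class = 2, t_int = 0.02,
                          seed = 11)
  ds <- generate_dataset(spec)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "events.rds")))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))

  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(labels), 6L)
  expect_equal(sort(as.integer(table(labels$class_label))), rep(2L, 3L))

  back <- read_dataset(dir)
  expect_equal(length(back$events), 6L)
  expect_identical(back$events[[2]]$series$counts,
                   ds$events[[2]]$series$counts)
  expect_equal(back$spec$name, "tubes_depth")
  expect_equal(back$config$dt, 1e-5)
})

test_that("run manifests record versions and checksums", {
  f <- tempfile()
  writeLines("hello", f)
  on.exit(unlink(f), add = TRUE)
  man <- run_manifest("simulate", list(seed = 1), files = f)
  expect_s3_class(man, "run_manifest")
  expect_equal(man$stage, "simulate")
  expect_match(man$checksums[[1]], "^[0-9a-f]{32}$")
  expect_true(nzchar(man$package_version))
})

test_that("the command-line entry point ships with the package", {
  cli <- system.file("cli", "speckleclass", package = "speckleclass")
  expect_true(nzchar(cli))
  first <- readLines(cli, n = 1L)
  expect_match(first, "Rscript")
})
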