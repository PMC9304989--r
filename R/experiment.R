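#' Simulate and correlate an experiment without retaining photon records
#'
#' Streams through the event plan of `spec`: each event's photon record is
#' simulated, reduced to its fiber-averaged autocorrelation features at
#' every integration time of the spec, and discarded. This keeps the
#' memory footprint at one event's counts (a few megabytes) instead of
#' the whole dataset (gigabytes at benchmark sizes), and gives identical
#' features to [generate_dataset()] followed by [assemble_features()]
#' because the per-event seeds come from the same plan.
#'
#' @param spec an [experiment_spec()] or experiment name.
#' @param config a [sim_config()].
#' @param probe probe geometry.
#' @param grid panel grid.
#' @param normalization passed to the feature assembly (default
#'   `"excess"`).
#' @return A named list, one element per integration time (names
#'   `as.character(spec$t_int)`), each as returned by
#'   [assemble_features()].
#' @export
stream_features <- function(spec, config = sim_config(),
                            probe = make_probe(), grid = panel_grid(),
                            normalization = "excess") {
  if (is.character(spec)) spec <- experiment_spec(spec)
  tissue <- tissue_preset(spec$tissue)
  plan <- dataset_plan(spec, spec$seed)
  grids <- lapply(spec$t_int, function(ti)
    lag_grid(config$dt, ti, tau_expected = tissue$tau_c_baseline))
  per_event <- lapply(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    pattern <- .pattern_from_plan(spec, row, grid)
    series <- simulate_event(pattern, probe, tissue, config,
                             duration = spec$duration,
                             seed = row$event_seed)
    lapply(seq_along(grids), function(j)
      as.numeric(event_fiber_curves(series, grids[[j]],
                                    t_int = spec$t_int[j])))
  })
  out <- lapply(seq_along(grids), function(j) {
    feats <- do.call(rbind, lapply(per_event, `[[`, j))
    .finalize_features(feats, plan$class_label, plan$event_id,
                       grids[[j]], spec$t_int[j], normalization)
  })
  names(out) <- as.character(spec$t_int)
  out
}

#' Run a full in-silico classification experiment
#'
#' Orchestrates simulate -> correlate -> cluster -> evaluate for one
#' benchmark: generates the labeled event dataset, computes per-fiber
#' autocorrelation features at each requested integration time, fits the
#' deep clustering network and the classical comparator, and evaluates
#' both with permutation-matched accuracy.
#'
#' @param spec an [experiment_spec()] or experiment name.
#' @param methods character vector among `"dcn"`, `"tsne_like"`, `"pca"`.
#' @param config a [sim_config()].
#' @param dcn_overrides named list overriding [dcn_config()] defaults
#'   (e.g. epoch counts).
#' @param probe probe geometry.
#' @param dataset optionally, a pre-generated `decorrelation_dataset`
#'   (skips simulation; must match `spec`). When `NULL` (default) the
#'   events are streamed through [stream_features()], which never holds
#'   more than one photon record in memory.
#' @return An object of class `experiment_result`: `report` (data.frame
#'   with columns `t_int`, `method`, `accuracy`, `n_events`), `details`
#'   (per-condition cluster reports), `spec` and the root `seed`.
#' @export
run_experiment <- function(spec, methods = c("dcn", "tsne_like"),
                           config = sim_config(), dcn_overrides = list(),
                           probe = make_probe(), dataset = NULL) {
  if (is.character(spec)) spec <- experiment_spec(spec)
  methods <- match.arg(methods, c("dcn", "tsne_like", "pca"),
                       several.ok = TRUE)
  tissue <- tissue_preset(spec$tissue)
  fx_list <- if (is.null(dataset)) {
    stream_features(spec, config = config, probe = probe)
  } else {
    stats::setNames(lapply(spec$t_int, function(ti) {
      grid <- lag_grid(config$dt, ti, tau_expected = tissue$tau_c_baseline)
      assemble_features(dataset, grid, t_int = ti)
    }), as.character(spec$t_int))
  }
  report <- NULL
  details <- list()
  for (t_int in spec$t_int) {
    fx <- fx_list[[as.character(t_int)]]
    for (method in methods) {
      key <- sprintf("%s@%gs", method, t_int)
      if (method == "dcn") {
        cfg <- dcn_config(input_dim = ncol(fx$features), K = spec$K,
                          seed = derive_seed(spec$seed, 301L))
        for (nm in names(dcn_overrides)) cfg[[nm]] <- dcn_overrides[[nm]]
        fit <- dcn_fit(fx$features, cfg, truth = fx$labels)
        details[[key]] <- fit
        acc <- fit$report$accuracy
      } else {
        be <- baseline_embed(fx$features, method,
                             seed = derive_seed(spec$seed, 302L),
                             K = spec$K)
        rep_b <- cluster_report(be$labels, fx$labels,
                                embedding = be$embedding)
        details[[key]] <- rep_b
        acc <- rep_b$accuracy
      }
      report <- rbind(report, data.frame(
        t_int = t_int, method = method, accuracy = acc,
        n_events = nrow(fx$features)))
    }
  }
  structure(list(report = report, details = details, spec = spec,
                 seed = spec$seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s (accuracies printed at two decimals)\n",
              x$spec$name))
  r <- x$report
  r$accuracy <- sprintf("%.2f", r$accuracy)
  print(r, row.names = FALSE)
  invisible(x)
}

#' Write a dataset to a directory
#'
#' Writes `events.rds` (the per-event integer count arrays and metadata),
#' `labels.csv` (event id, class label, pattern kind) and `config.yaml`
#' (full parameter snapshot including the seed).
#'
#' @param dataset a `decorrelation_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset$events, file.path(dir, "events.rds"))
  labels <- data.frame(
    event_id = vapply(dataset$events, `[[`, numeric(1), "event_id"),
    class_label = vapply(dataset$events, `[[`, integer(1), "class_label"),
    pattern_kind = vapply(dataset$events, `[[`, character(1), "pattern_kind"))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  snapshot <- list(spec = unclass(dataset$spec),
                   config = unclass(dataset$config),
                   probe = unclass(dataset$probe)[c("n_fibers",
                                                    "sd_separation",
                                                    "pixels_per_fiber")],
                   seed = dataset$seed)
  yaml::write_yaml(snapshot, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return A `decorrelation_dataset`.
#' @export
read_dataset <- function(dir) {
  events <- readRDS(file.path(dir, "events.rds"))
  snap <- yaml::read_yaml(file.path(dir, "config.yaml"))
  spec <- do.call(experiment_spec, snap$spec[c("name", "per_class",
                                               "tissue", "t_int", "depth",
                                               "seed", "scale")])
  config <- do.call(sim_config, snap$config[c("seed", "beta", "mean_rate",
                                              "dark_rate", "g1_model",
                                              "scale")])
  probe <- do.call(make_probe, snap$probe)
  structure(list(events = events, plan = NULL, spec = spec, config = config,
                 probe = probe, seed = snap$seed),
            class = "decorrelation_dataset")
}

#' Run manifest for a pipeline invocation
#'
#' Records the configuration, package version, seeds and input/output
#' checksums of a stage, so deterministic stages can be re-verified.
#'
#' @param stage stage name.
#' @param config list of parameters.
#' @param files character vector of output file paths to checksum.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(stage, config, files = character()) {
  sums <- vapply(files, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, character(1))
  structure(list(stage = stage,
                 package_version = as.character(utils::packageVersion("speckleclass")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = config, checksums = sums),
            class = "run_manifest")
}
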