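#' Specification of an in-silico experiment
#'
#' Names one of the four built-in benchmark studies and its conditions:
#'
#' * `letters_DUKE`: four letter-shaped panel patterns ("D", "U", "K",
#'   "E"), mirror flip rate 5 kHz, default 200 events per class.
#' * `circles`: four spatio-temporal classes crossing circle size with
#'   flip rate (5/10 kHz), default 200 events per class.
#' * `tubes_9combo`: two flow tubes, each in one of three states
#'   (0 / 0.7 / 1.4 mm/s), giving nine combinations, default 100 events
#'   per class.
#' * `tubes_depth`: both tubes share one of three flow states
#'   (0 / 1 / 2 mm/s) at a configurable depth, default 100 per class.
#'
#' @param name experiment name.
#' @param per_class events per class (>= 0).
#' @param tissue tissue preset name; defaults follow the benchmark
#'   conventions (DMD studies on `"tissue1"`, tube studies on `"tissue2"`).
#' @param t_int integration times (s) at which curves are computed.
#' @param depth tube depth in mm (tube experiments only).
#' @param seed root seed.
#' @param scale sensor scale, `"reduced"` or `"full"`.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name = c("letters_DUKE", "circles",
                                     "tubes_9combo", "tubes_depth"),
                            per_class = NULL, tissue = NULL,
                            t_int = NULL, depth = 5, seed = 1L,
                            scale = "reduced") {
  name <- match.arg(name)
  defaults <- switch(name,
    letters_DUKE = list(per_class = 200L, tissue = "tissue1",
                        t_int = c(0.2, 0.4), K = 4L),
    circles = list(per_class = 200L, tissue = "tissue1",
                   t_int = c(0.2, 0.4), K = 4L),
    tubes_9combo = list(per_class = 100L, tissue = "tissue2",
                        t_int = c(0.1, 0.2), K = 9L),
    tubes_depth = list(per_class = 100L, tissue = "tissue2",
                       t_int = c(0.2), K = 3L)
  )
  per_class <- as.integer(per_class %||% defaults$per_class)
  if (per_class < 0) stop("`per_class` must be >= 0")
  t_int <- t_int %||% defaults$t_int
  if (any(t_int <= 0)) stop("integration times must be positive")
  structure(
    list(name = name, per_class = per_class,
         tissue = tissue %||% defaults$tissue,
         t_int = sort(t_int), duration = max(t_int),
         K = defaults$K, depth = depth,
         seed = as.numeric(seed), scale = scale),
    class = "experiment_spec"
  )
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> %s: %d classes x %d events, tissue %s, T_int {%s} s\n",
              x$name, x$K, x$per_class, x$tissue,
              paste(x$t_int, collapse = ", ")))
  invisible(x)
}

#' Plan the events of an experiment without simulating photons
#'
#' Draws the per-event ground-truth classes and within-class nuisance
#' parameters (letter placement jitter, circle offsets, flow-rate jitter)
#' and the per-event seeds, then shuffles the event order
#' deterministically. This is the cheap, label-level view of a dataset;
#' [generate_dataset()] turns each row into a photon record.
#'
#' @param spec an [experiment_spec()] (or a name accepted by it).
#' @param seed root seed (defaults to the spec's).
#' @return A data.frame with one row per event: `event_id`, `class_label`,
#'   `event_seed` and the pattern nuisance columns for the experiment
#'   kind.
#' @export
dataset_plan <- function(spec, seed = spec$seed) {
  if (is.character(spec)) spec <- experiment_spec(spec)
  n <- spec$K * spec$per_class
  if (n == 0L) {
    return(data.frame(event_id = integer(), class_label = integer(),
                      event_seed = numeric()))
  }
  class_label <- rep(seq_len(spec$K), each = spec$per_class)
  plan <- with_seed(derive_seed(seed, 101L), {
    base <- data.frame(class_label = class_label)
    if (spec$name %in% c("letters_DUKE", "circles")) {
      base$shift_x <- stats::runif(n, -0.5, 0.5) * if (spec$name == "circles") 2 else 1
      base$shift_y <- stats::runif(n, -0.5, 0.5) * if (spec$name == "circles") 2 else 1
      base$rot <- if (spec$name == "letters_DUKE") stats::runif(n, -0.15, 0.15) else 0
      base$scale <- if (spec$name == "letters_DUKE") stats::runif(n, 0.9, 1.1) else 1
    } else {
      states <- if (spec$name == "tubes_9combo") c(0, 0.7, 1.4) else c(0, 1, 2)
      if (spec$name == "tubes_9combo") {
        base$flow_a <- states[(class_label - 1L) %/% 3L + 1L]
        base$flow_b <- states[(class_label - 1L) %% 3L + 1L]
      } else {
        base$flow_a <- states[class_label]
        base$flow_b <- states[class_label]
      }
      # syringe-pump speed jitter, ~3 percent
      base$flow_a <- base$flow_a * exp(stats::rnorm(n, 0, 0.03))
      base$flow_b <- base$flow_b * exp(stats::rnorm(n, 0, 0.03))
    }
    base[sample.int(n), , drop = FALSE]
  })
  plan$event_id <- seq_len(n)
  plan$event_seed <- vapply(seq_len(n), function(i) derive_seed(seed, 500L + i),
                            numeric(1))
  rownames(plan) <- NULL
  plan[, c("event_id", "class_label", "event_seed",
           setdiff(names(plan), c("event_id", "class_label", "event_seed")))]
}

.pattern_from_plan <- function(spec, row, grid) {
  switch(spec$name,
    letters_DUKE = letter_pattern(c("D", "U", "K", "E")[row$class_label],
                                  grid = grid,
                                  shift = c(row$shift_x, row$shift_y),
                                  rot = row$rot, scale = row$scale),
    circles = circles_pattern(row$class_label, grid = grid,
                              shift = c(row$shift_x, row$shift_y)),
    tubes_9combo = tubes_pattern(c(row$flow_a, row$flow_b), grid = grid,
                                 depth = spec$depth,
                                 class_label = row$class_label),
    tubes_depth = tubes_pattern(c(row$flow_a, row$flow_b), grid = grid,
                                depth = spec$depth,
                                class_label = row$class_label)
  )
}

#' Generate a labeled dataset of decorrelation events
#'
#' Simulates the photon record of every event in the plan of `spec`.
#' Label counts are exactly `per_class` per class and the event order is
#' shuffled deterministically by the seed.
#'
#' @param spec an [experiment_spec()] or experiment name.
#' @param seed root seed (defaults to the spec's seed).
#' @param config a [sim_config()]; its seed is ignored in favor of the
#'   per-event seeds derived here.
#' @param probe probe geometry.
#' @param grid panel grid.
#' @return A list of class `decorrelation_dataset`: `events` (each with
#'   `series`, `class_label`, `tau_p`, `event_id`), `plan`, `spec`,
#'   `probe`, `config`.
#' @export
generate_dataset <- function(spec, seed = NULL, config = sim_config(),
                             probe = make_probe(), grid = panel_grid()) {
  if (is.character(spec)) spec <- experiment_spec(spec)
  seed <- seed %||% spec$seed
  tissue <- tissue_preset(spec$tissue)
  plan <- dataset_plan(spec, seed)
  events <- lapply(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    pattern <- .pattern_from_plan(spec, row, grid)
    series <- simulate_event(pattern, probe, tissue, config,
                             duration = spec$duration, seed = row$event_seed)
    list(event_id = row$event_id, class_label = row$class_label,
         series = series, tau_p = attr(series, "tau_p"),
         pattern_kind = pattern$kind)
  })
  structure(
    list(events = events, plan = plan, spec = spec, probe = probe,
         config = config, seed = seed),
    class = "decorrelation_dataset"
  )
}

#' @export
print.decorrelation_dataset <- function(x, ...) {
  cat(sprintf("<decorrelation_dataset> %s: %d events, %d classes\n",
              x$spec$name, length(x$events), x$spec$K))
  invisible(x)
}
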