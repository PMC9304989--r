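#' Lag grid for autocorrelation estimation
#'
#' Default is 24 log-spaced lags from one bin up to
#' `min(5 * tau_expected, T_int / 10)`, which spans the decay of the
#' correlation with few points. Lags are integer multiples of the bin
#' width; duplicates arising from rounding are collapsed, so the grid can
#' hold fewer points than requested at very coarse bin widths.
#'
#' @param dt bin width, s.
#' @param t_int integration time, s.
#' @param tau_expected expected decorrelation time, s (default 1e-3).
#' @param n number of lags requested (default 24).
#' @param scheme `"log_spaced"` (default) or `"linear"`.
#' @return An object of class `lag_grid` with integer `bins` (strictly
#'   increasing, starting at 1) and `lags_s = bins * dt`.
#' @export
lag_grid <- function(dt, t_int, tau_expected = 1e-3, n = 24L,
                     scheme = c("log_spaced", "linear")) {
  scheme <- match.arg(scheme)
  stop_if_not_scalar_positive(dt, "dt")
  stop_if_not_scalar_positive(t_int, "t_int")
  max_lag <- max(2, floor(min(5 * tau_expected, t_int / 10) / dt))
  bins <- if (scheme == "log_spaced") {
    unique(round(exp(seq(0, log(max_lag), length.out = n))))
  } else {
    unique(round(seq(1, max_lag, length.out = n)))
  }
  bins <- sort(as.integer(bins))
  structure(list(bins = bins, lags_s = bins * dt, dt = dt, scheme = scheme),
            class = "lag_grid")
}

#' Per-pixel intensity autocorrelation
#'
#' Estimates the normalized temporal intensity autocorrelation
#' `g2(tau) = <I(t) I(t + tau)> / <I>^2` of each pixel's photon-count
#' sequence over an integration window. Two normalization conventions are
#' available for the finite window: `"symmetric"` (default) divides the
#' lag products by the means of the two overlapped segments, which removes
#' most finite-window bias; `"whole_window"` divides by the squared mean
#' of the full window, the literal time-average form. A window whose
#' relevant mean is zero (no photons) yields `NA` at that lag rather than
#' an error, and such entries are skipped by [fiber_average()].
#'
#' @param counts integer vector (one pixel) or matrix (bins x pixels).
#' @param grid a [lag_grid()]; all lags must be shorter than the window.
#' @param t_int integration time, s; defaults to the full record.
#' @param offset window start offset, s.
#' @param normalization `"symmetric"` or `"whole_window"`.
#' @return A matrix (lags x pixels) of class `g2_curve` with attributes
#'   `lags_s`, `t_int` and `source = "pixel"`.
#' @export
pixel_autocorrelation <- function(counts, grid, t_int = NULL, offset = 0,
                                  normalization = c("symmetric",
                                                    "whole_window")) {
  normalization <- match.arg(normalization)
  if (is.vector(counts)) counts <- matrix(as.integer(counts), ncol = 1L)
  dt <- grid$dt
  n_total <- nrow(counts)
  t_int <- t_int %||% (n_total * dt)
  w <- as.integer(round(t_int / dt))
  o <- as.integer(round(offset / dt))
  if (o + w > n_total) stop("integration window exceeds the record")
  if (any(grid$bins >= w)) stop("all lags must be shorter than the window")
  win <- counts[(o + 1L):(o + w), , drop = FALSE]
  storage.mode(win) <- "integer"
  g2 <- .cpp_g2_counts(win, grid$bins, normalization == "symmetric")
  structure(g2, lags_s = grid$lags_s, t_int = w * dt, source = "pixel",
            normalization = normalization, class = "g2_curve")
}

#' Build the pixel-to-fiber look-up table from a flat-field image
#'
#' Pixels whose time-averaged count exceeds `threshold_fraction` of the
#' image maximum are assigned to the nearest declared fiber spot centroid
#' (ties to the lowest fiber index); sub-threshold pixels stay unmapped.
#'
#' @param mean_image numeric vector of per-pixel time-averaged counts
#'   (column-major pixel order of the layout).
#' @param probe a [make_probe()] geometry (declares the fiber count).
#' @param threshold_fraction fraction of the image maximum, in (0, 1).
#' @param layout a [make_sensor_layout()]; supplies pixel coordinates and
#'   declared spot centroids.
#' @return An object of class `fiber_lookup`: `pixel_to_fiber` (integer,
#'   `NA` = unmapped) and `Q_p` (pixels per fiber).
#' @export
build_lookup_table <- function(mean_image, probe, threshold_fraction = 0.2,
                               layout = make_sensor_layout(probe)) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("`threshold_fraction` must lie in (0, 1)")
  if (length(mean_image) != layout$n_pixels)
    stop("`mean_image` length does not match the sensor layout")
  bright <- which(mean_image > threshold_fraction * max(mean_image))
  if (length(bright) == 0L) stop("no detectable fiber spots above threshold")
  assign <- rep(NA_integer_, layout$n_pixels)
  cx <- layout$centroids[, 1]; cy <- layout$centroids[, 2]
  for (px in bright) {
    d2 <- (layout$pixel_xy[px, 1] - cx)^2 + (layout$pixel_xy[px, 2] - cy)^2
    assign[px] <- which.min(d2) # which.min takes the first (lowest) on ties
  }
  Q_p <- tabulate(assign, nbins = probe$n_fibers)
  structure(list(pixel_to_fiber = assign, Q_p = Q_p), class = "fiber_lookup")
}

#' Fiber lookup from the simulator's ground-truth layout
#'
#' @param layout a [make_sensor_layout()].
#' @return A `fiber_lookup` using the layout's exact pixel mapping.
#' @export
lookup_from_layout <- function(layout) {
  structure(list(pixel_to_fiber = layout$pixel_to_fiber,
                 Q_p = tabulate(layout$pixel_to_fiber)),
            class = "fiber_lookup")
}

#' Ensemble-averaged autocorrelation of one fiber
#'
#' Averages the per-pixel `g2` curves of the `Q_p` pixels mapped to a
#' fiber, lag by lag, skipping flagged-undefined (`NA`) entries and
#' recording the effective pixel count per lag.
#'
#' @param pixel_curves a `g2_curve` matrix (lags x pixels) covering the
#'   whole sensor.
#' @param lookup a `fiber_lookup`.
#' @param fiber_index which fiber to average.
#' @return A `g2_curve` vector (one column) with attribute `n_eff`.
#' @export
fiber_average <- function(pixel_curves, lookup, fiber_index) {
  px <- which(lookup$pixel_to_fiber == fiber_index)
  if (length(px) == 0L) stop(sprintf("fiber %d has no mapped pixels", fiber_index))
  sub <- unclass(pixel_curves)[, px, drop = FALSE]
  avg <- rowMeans(sub, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  structure(matrix(avg, ncol = 1L), lags_s = attr(pixel_curves, "lags_s"),
            t_int = attr(pixel_curves, "t_int"), source = "fiber",
            n_eff = rowSums(!is.na(sub)), class = "g2_curve")
}

#' Extract an integration window from a photon record
#'
#' @param series a `photon_frame_series`.
#' @param t_int window length, s.
#' @param offset window start, s.
#' @return A `photon_frame_series` covering exactly `floor(t_int / dt)`
#'   bins starting at `offset`.
#' @export
window_event <- function(series, t_int, offset = 0) {
  # small epsilon guards against 0.02 / 1e-5 = 1999.999... in doubles
  w <- as.integer(floor(t_int / series$dt + 1e-9))
  o <- as.integer(round(offset / series$dt))
  if (o + w > nrow(series$counts)) stop("window exceeds the record")
  out <- series
  out$counts <- series$counts[(o + 1L):(o + w), , drop = FALSE]
  out$duration <- w * series$dt
  out
}

#' All per-fiber averaged curves of one event
#'
#' Runs the per-pixel estimator on an integration window and ensemble
#' averages within each fiber.
#'
#' @param series a `photon_frame_series`.
#' @param grid a [lag_grid()].
#' @param lookup a `fiber_lookup` (defaults to the simulator layout).
#' @inheritParams pixel_autocorrelation
#' @return Matrix (lags x fibers) of fiber-averaged `g2` values.
#' @export
event_fiber_curves <- function(series, grid, lookup = NULL, t_int = NULL,
                               offset = 0,
                               normalization = c("symmetric",
                                                 "whole_window")) {
  normalization <- match.arg(normalization)
  lookup <- lookup %||% lookup_from_layout(series$layout)
  px <- pixel_autocorrelation(series$counts, grid, t_int, offset,
                              normalization)
  nf <- length(lookup$Q_p)
  vapply(seq_len(nf), function(p) as.numeric(fiber_average(px, lookup, p)),
         numeric(length(grid$bins)))
}

#' Assemble the per-event feature matrix
#'
#' Flattens each event's fiber-averaged curves (fiber-major: all lags of
#' fiber 1, then fiber 2, ...) into one row. The default normalization
#' subtracts 1 and divides by the per-event mean zero-lag excess (mean
#' over fibers of `g2` at the first lag minus one), which removes the
#' event's overall coherence/intensity scale while keeping the decay
#' structure. Events with any non-finite feature entry are dropped with a
#' warning rather than imputed.
#'
#' @param dataset a `decorrelation_dataset`, or a list of events.
#' @param grid a [lag_grid()].
#' @param t_int integration time, s.
#' @param normalization `"excess"` (default) or `"none"`.
#' @param offset window start, s.
#' @return A list with `features` (N x (fibers * lags) matrix), `labels`
#'   (integer), `event_ids` and `grid`.
#' @export
assemble_features <- function(dataset, grid, t_int = NULL,
                              normalization = c("excess", "none"),
                              offset = 0) {
  normalization <- match.arg(normalization)
  events <- if (inherits(dataset, "decorrelation_dataset")) dataset$events else dataset
  L <- length(grid$bins)
  rows <- lapply(events, function(ev) {
    curves <- event_fiber_curves(ev$series, grid, t_int = t_int,
                                 offset = offset)
    as.numeric(curves) # column-major = fiber-major flattening
  })
  feats <- do.call(rbind, rows)
  labels <- vapply(events, function(ev) ev$class_label, integer(1))
  ids <- vapply(events, function(ev) ev$event_id, numeric(1))
  .finalize_features(feats, labels, ids, grid, t_int, normalization)
}

# Shared tail of feature assembly: drop rows with undefined entries, then
# apply the per-event excess normalization.
.finalize_features <- function(feats, labels, ids, grid, t_int,
                               normalization) {
  L <- length(grid$bins)
  ok <- apply(is.finite(feats), 1L, all)
  if (!all(ok)) {
    warning(sprintf("dropping %d event(s) with undefined correlation entries",
                    sum(!ok)))
    feats <- feats[ok, , drop = FALSE]
    labels <- labels[ok]
    ids <- ids[ok]
  }
  if (normalization == "excess") {
    zl <- seq(1, ncol(feats), by = L) # first lag of every fiber
    feats <- feats - 1
    scale <- rowMeans(feats[, zl, drop = FALSE])
    scale[scale <= 0] <- 1
    feats <- feats / scale
  }
  list(features = feats, labels = labels, event_ids = ids, grid = grid,
       t_int = t_int, normalization = normalization)
}
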