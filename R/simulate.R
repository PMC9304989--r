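#' Simulate a stationary complex speckle field trace
#'
#' Synthesizes a zero-mean circular complex Gaussian process whose field
#' autocorrelation matches a prescribed `g1` curve, by circulant embedding
#' of the covariance sequence: the target correlations on `0..n_bins-1`
#' bins are wrapped into a circulant covariance whose spectrum (FFT of the
#' first row) drives independent complex-Gaussian spectral amplitudes.
#' Small negative spectral values arising from the embedding are clipped
#' to zero; for the correlation models used here the clipped mass is
#' negligible and the empirical autocorrelation test bounds the error.
#'
#' @param g1_curve function of lag in seconds returning `g1` values, e.g.
#'   `function(tau) field_g1(tau, "exponential", list(tau_c = 1e-3))`.
#' @param n_bins number of time bins (>= 2).
#' @param dt bin width in seconds.
#' @param seed integer seed; identical arguments give bit-identical traces.
#' @return Complex vector of length `n_bins` with unit mean square
#'   modulus in expectation.
#' @export
simulate_field_trace <- function(g1_curve, n_bins, dt, seed) {
  if (!is.function(g1_curve)) stop("`g1_curve` must be a function of lag")
  if (n_bins < 2) stop("`n_bins` must be at least 2")
  stop_if_not_scalar_positive(dt, "dt")
  r <- g1_curve((0:(n_bins - 1)) * dt)
  if (any(!is.finite(r))) stop("correlation model is not evaluable on the window")
  m <- 2L * n_bins
  circ <- c(r, 0, rev(r[-1]))
  lambda <- pmax(Re(stats::fft(circ)), 0)
  z <- with_seed(seed, complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))) /
    sqrt(2)
  trace <- stats::fft(sqrt(lambda) * z) / sqrt(m)
  trace[seq_len(n_bins)]
}

#' Sample photon counts from an intensity trace
#'
#' Conditionally Poisson photon detection: counts in bin `t` are Poisson
#' with mean `mean_rate * I(t) / mean(I)`, so the time-averaged count per
#' bin equals `mean_rate` regardless of the intensity scale.
#'
#' @param intensity non-negative intensity trace.
#' @param mean_rate target photons per bin.
#' @param seed integer seed.
#' @return Integer vector of counts, same length as `intensity`.
#' @export
sample_photon_counts <- function(intensity, mean_rate, seed) {
  if (any(intensity < 0)) stop("`intensity` must be non-negative")
  stop_if_not_scalar_positive(mean_rate, "mean_rate")
  mbar <- mean(intensity)
  if (mbar == 0) return(integer(length(intensity)))
  with_seed(seed, stats::rpois(length(intensity), mean_rate * intensity / mbar))
}

# Per-fiber field correlation model used by the general (non-AR) path.
.g1_fun_for_tau <- function(tau_p, config, tissue, probe) {
  switch(config$g1_model,
    exponential = function(tau)
      field_g1(tau, "exponential", list(tau_c = tau_p)),
    stretched_exponential = function(tau)
      field_g1(tau, "stretched_exponential",
               list(tau_c = tau_p, gamma = config$g1_params$gamma %||% 0.7)),
    semi_infinite_cde = {
      # map the effective decorrelation time onto the Brownian flow index:
      # alpha_Db scales inversely with tau relative to the unperturbed medium
      p <- config$g1_params %||% list()
      aDb <- (p$alpha_Db %||% 1e-6) * tissue$tau_c_baseline / tau_p
      function(tau) field_g1(tau, "semi_infinite_cde", list(
        rho = probe$sd_separation, mu_a = tissue$mu_a,
        mu_s_prime = tissue$mu_s_prime,
        k0 = p$k0 %||% (2 * pi * 1.33 / 670e-6), alpha_Db = aDb))
    })
}

#' Simulate one decorrelation event
#'
#' Produces the raw photon-count record of a single transient perturbation:
#' every pixel mapped to fiber `p` carries an independent speckle
#' realization decorrelating at that fiber's effective time `tau_p`
#' (from [pattern_to_fiber_tau()]); unmapped pixels record dark counts
#' only. The detected photon rate is attenuated relative to the reference
#' preset by the diffuse-reflectance ratio of the tissue, so more turbid
#' presets are photon-starved as well as less sensitive.
#'
#' For the default exponential field model the speckle process is an exact
#' complex AR(1) generated in compiled code; other field models go through
#' [simulate_field_trace()] per pixel.
#'
#' @param pattern a `perturbation_pattern`.
#' @param probe a [make_probe()] geometry.
#' @param tissue a [tissue_preset()].
#' @param config a [sim_config()].
#' @param duration record length in seconds (>= one bin).
#' @param seed integer seed (default derived from `config$seed`).
#' @return An object of class `photon_frame_series`: integer `counts`
#'   (`n_bins x n_pixels`), `dt`, `n_pixels`, `duration`, the sensor
#'   `layout`, and the ground-truth per-fiber `tau_p` as an attribute.
#' @export
simulate_event <- function(pattern, probe, tissue, config = sim_config(),
                           duration = 0.2, seed = config$seed) {
  dt <- config$dt
  n_bins <- as.integer(round(duration / dt))
  if (n_bins < 1) stop("`duration` must cover at least one bin")
  layout <- make_sensor_layout(probe, config$scale)
  kernel <- sensitivity_kernel(probe, pattern$grid)
  tau_p <- pattern_to_fiber_tau(pattern, kernel, tissue)

  ref <- tissue_preset("tissue1")
  rate_scale <- cw_reflectance(probe$sd_separation, tissue$mu_a, tissue$mu_s_prime) /
    cw_reflectance(probe$sd_separation, ref$mu_a, ref$mu_s_prime)
  pix_fiber <- layout$pixel_to_fiber
  mapped <- !is.na(pix_fiber)
  rate_px <- ifelse(mapped, config$mean_rate * rate_scale, 0)

  if (config$g1_model == "exponential") {
    rho_px <- ifelse(mapped, exp(-dt / tau_p[ifelse(mapped, pix_fiber, 1L)]), 0)
    counts <- .cpp_speckle_counts(n_bins, rho_px, rate_px, config$beta,
                                  config$dark_rate, derive_seed(seed, 1L))
  } else {
    counts <- matrix(0L, n_bins, layout$n_pixels)
    s <- sqrt(config$beta)
    for (px in seq_len(layout$n_pixels)) {
      px_seed <- derive_seed(seed, 1000L + px)
      if (!mapped[px]) {
        counts[, px] <- with_seed(px_seed,
                                  stats::rpois(n_bins, config$dark_rate))
        next
      }
      g1f <- .g1_fun_for_tau(tau_p[pix_fiber[px]], config, tissue, probe)
      E <- simulate_field_trace(g1f, n_bins, dt, px_seed)
      X <- Mod(E)^2 / mean(Mod(E)^2)
      lam <- rate_px[px] * ((1 - s) + s * X) + config$dark_rate
      counts[, px] <- with_seed(derive_seed(px_seed, 7L),
                                stats::rpois(n_bins, lam))
    }
  }
  structure(
    list(counts = counts, dt = dt, n_pixels = layout$n_pixels,
         duration = n_bins * dt, layout = layout),
    tau_p = tau_p,
    class = "photon_frame_series"
  )
}

#' @export
print.photon_frame_series <- function(x, ...) {
  cat(sprintf("<photon_frame_series> %d bins x %d pixels, dt = %g s (%.3g s)\n",
              nrow(x$counts), x$n_pixels, x$dt, x$duration))
  invisible(x)
}
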