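#' Construct the detection probe geometry
#'
#' The probe places `n_fibers` multimode detection fibers at equal angular
#' spacing on a circle of radius `sd_separation` around a central source
#' fiber. Each detection fiber is imaged onto a block of SPAD pixels, so
#' every fiber contributes `pixels_per_fiber` independent speckle
#' measurements.
#'
#' @param n_fibers number of detection fibers (default 12).
#' @param sd_separation source-detector separation in mm (default 9).
#' @param pixels_per_fiber SPAD pixels imaged per fiber (default 8).
#' @param fiber_core fiber core diameter in micrometers (default 250).
#' @return An object of class `probe_geometry` with fields `n_fibers`,
#'   `sd_separation`, `fiber_core`, `pixels_per_fiber`, `fiber_angles`
#'   (radians, strictly increasing in `[0, 2*pi)`), and fiber positions
#'   `fiber_x`, `fiber_y` in mm.
#' @examples
#' probe <- make_probe(12, 9, 8)
#' probe$fiber_angles[2] - probe$fiber_angles[1] # 30 degrees
#' @export
make_probe <- function(n_fibers = 12L, sd_separation = 9,
                       pixels_per_fiber = 8L, fiber_core = 250) {
  if (!is.numeric(n_fibers) || n_fibers < 1 || n_fibers != round(n_fibers))
    stop("`n_fibers` must be a positive integer")
  stop_if_not_scalar_positive(sd_separation, "sd_separation")
  if (!is.numeric(pixels_per_fiber) || pixels_per_fiber < 1 ||
      pixels_per_fiber != round(pixels_per_fiber))
    stop("`pixels_per_fiber` must be a positive integer")
  stop_if_not_scalar_positive(fiber_core, "fiber_core")
  n_fibers <- as.integer(n_fibers)
  angles <- 2 * pi * (seq_len(n_fibers) - 1L) / n_fibers
  structure(
    list(
      n_fibers = n_fibers,
      sd_separation = sd_separation,
      fiber_core = fiber_core,
      pixels_per_fiber = as.integer(pixels_per_fiber),
      fiber_angles = angles,
      fiber_x = sd_separation * cos(angles),
      fiber_y = sd_separation * sin(angles)
    ),
    class = "probe_geometry"
  )
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(
    "<probe_geometry> %d fibers at rho = %g mm, %d px/fiber, %g um core\n",
    x$n_fibers, x$sd_separation, x$pixels_per_fiber, x$fiber_core))
  invisible(x)
}

#' Optical presets for the dynamic scattering phantom
#'
#' Two microsphere-suspension presets bracket typical tissue optics:
#' `"tissue1"` (reduced scattering 0.7 mm^-1, absorption 0.01 mm^-1) and
#' `"tissue2"` (1.2 mm^-1, 0.02 mm^-1). The baseline field decorrelation
#' time of the unperturbed medium scales inversely with the reduced
#' scattering coefficient, as in diffusing-wave spectroscopy where the
#' accumulated phase decorrelation grows with the number of scattering
#' events per path; `"tissue1"` is anchored at 1 ms.
#'
#' Increased turbidity has two further consequences that the simulator
#' carries through: perturbations under the phantom couple more weakly to
#' the surface signal (sensitivity scale `mu_s_ref / mu_s_prime`), and
#' fewer photons reach the detectors (continuous-wave diffuse reflectance
#' ratio at the source-detector separation, see [cw_reflectance()]).
#'
#' @param name `"tissue1"` or `"tissue2"`.
#' @return An object of class `tissue_preset` with fields `name`,
#'   `mu_s_prime`, `mu_a` (mm^-1) and `tau_c_baseline` (s).
#' @export
tissue_preset <- function(name = c("tissue1", "tissue2")) {
  name <- match.arg(name)
  pars <- switch(name,
    tissue1 = list(mu_s_prime = 0.7, mu_a = 0.01),
    tissue2 = list(mu_s_prime = 1.2, mu_a = 0.02)
  )
  tau_ref <- 1e-3 # s, anchored at mu_s_prime = 0.7 mm^-1
  structure(
    list(
      name = name,
      mu_s_prime = pars$mu_s_prime,
      mu_a = pars$mu_a,
      tau_c_baseline = tau_ref * 0.7 / pars$mu_s_prime
    ),
    class = "tissue_preset"
  )
}

#' @export
print.tissue_preset <- function(x, ...) {
  cat(sprintf("<tissue_preset> %s: mu_s' = %g mm^-1, mu_a = %g mm^-1, tau_c = %g s\n",
              x$name, x$mu_s_prime, x$mu_a, x$tau_c_baseline))
  invisible(x)
}

#' Continuous-wave diffuse reflectance at a source-detector separation
#'
#' Semi-infinite diffusion-theory reflectance with extrapolated boundary,
#' used to scale the detected photon rate between tissue presets (absolute
#' calibration cancels in the ratio).
#'
#' @param rho source-detector separation, mm.
#' @param mu_a absorption coefficient, mm^-1.
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @param Reff effective Fresnel reflection coefficient (0.493 for a
#'   tissue-air interface with relative refractive index ~1.33).
#' @return Reflectance (photons per unit area, arbitrary common scale).
#' @export
cw_reflectance <- function(rho, mu_a, mu_s_prime, Reff = 0.493) {
  z0 <- 1 / mu_s_prime
  zb <- 2 * (1 + Reff) / (3 * mu_s_prime * (1 - Reff))
  mu_eff <- sqrt(3 * mu_a * mu_s_prime)
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
     (z0 + 2 * zb) * (mu_eff + 1 / rb) * exp(-mu_eff * rb) / rb^2) / (4 * pi)
}

#' Simulation configuration
#'
#' Bundles the sensor-level parameters of the synthetic photon-count
#' generator. The `reduced` scale (default) uses 10 microsecond bins; the
#' `full` scale uses the hardware bin width of 1.5 microseconds with a
#' 32 x 32 sensor. `mean_rate` is the time-averaged photon count per bin
#' per mapped pixel for the reference preset (`tissue1`); presets with
#' lower diffuse reflectance are attenuated accordingly.
#'
#' @param seed integer root seed.
#' @param beta speckle coherence factor in (0, 1]; ~0.9 for one speckle
#'   mapped per pixel with residual polarization mixing.
#' @param mean_rate photons per bin per pixel at the reference preset.
#'   The reduced-scale default 0.03 (3000 counts/s at 10 us bins) matches
#'   the photon-starved regime of deep-tissue speckle detection.
#' @param dark_rate dark counts per bin per pixel (default 5e-4, i.e. 50
#'   counts/s at the reduced bin width).
#' @param g1_model field autocorrelation model used for the speckle
#'   dynamics; `"exponential"` (default), `"stretched_exponential"` or
#'   `"semi_infinite_cde"`.
#' @param scale `"reduced"` (default) or `"full"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, beta = 0.9, mean_rate = 0.03,
                       dark_rate = 5e-4,
                       g1_model = c("exponential", "stretched_exponential",
                                    "semi_infinite_cde"),
                       scale = c("reduced", "full")) {
  g1_model <- match.arg(g1_model)
  scale <- match.arg(scale)
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta > 1)
    stop("`beta` must lie in (0, 1]")
  stop_if_not_scalar_positive(mean_rate, "mean_rate")
  if (dark_rate < 0) stop("`dark_rate` must be non-negative")
  structure(
    list(
      seed = as.numeric(seed),
      beta = beta,
      mean_rate = mean_rate,
      dark_rate = dark_rate,
      g1_model = g1_model,
      scale = scale,
      dt = if (scale == "reduced") 1e-5 else 1.5e-6
    ),
    class = "sim_config"
  )
}

#' Sensor layout: which pixel sees which fiber
#'
#' Arranges the fiber spots as rectangular pixel blocks on a square SPAD
#' grid, mirroring how a fiber bundle is imaged onto contiguous pixel
#' regions. At the reduced default (12 fibers, 8 pixels each) this gives a
#' 10 x 12 grid with twelve 2 x 4 pixel blocks (96 mapped pixels plus a
#' 2-column unmapped margin that records dark counts only); the full scale
#' pads to a 32 x 32 grid. Spot centroids are the block centers, which is
#' what the flat-field look-up-table builder recovers.
#'
#' @param probe a [make_probe()] geometry.
#' @param scale `"reduced"` or `"full"`.
#' @return An object of class `sensor_layout` with fields `nx`, `ny`,
#'   `n_pixels`, `pixel_to_fiber` (integer vector, `NA` for unmapped
#'   pixels, column-major pixel order), `centroids` (fiber spot centers in
#'   pixel coordinates) and `pixel_xy` (pixel centers).
#' @export
make_sensor_layout <- function(probe, scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  ppf <- probe$pixels_per_fiber
  nf <- probe$n_fibers
  # block shape: as square as possible
  bw <- max(1L, as.integer(floor(sqrt(ppf))))
  while (ppf %% bw != 0L) bw <- bw - 1L
  bh <- as.integer(ppf / bw)
  # grid of blocks, as square as possible
  nbx <- as.integer(ceiling(sqrt(nf)))
  nby <- as.integer(ceiling(nf / nbx))
  nx <- nbx * bw + 2L # unmapped margin exercises the dark-pixel path
  ny <- nby * bh
  if (scale == "full") { nx <- max(nx, 32L); ny <- max(ny, 32L) }
  pixel_to_fiber <- rep(NA_integer_, nx * ny)
  centroids <- matrix(NA_real_, nf, 2)
  for (p in seq_len(nf)) {
    bx <- (p - 1L) %% nbx
    by <- (p - 1L) %/% nbx
    cols <- bx * bw + seq_len(bw)
    rows <- by * bh + seq_len(bh)
    idx <- as.vector(outer(rows, (cols - 1L) * ny, `+`))
    pixel_to_fiber[idx] <- p
    centroids[p, ] <- c(mean(cols), mean(rows))
  }
  pixel_xy <- cbind(
    x = rep(seq_len(nx), each = ny),
    y = rep(seq_len(ny), times = nx)
  )
  structure(
    list(nx = nx, ny = ny, n_pixels = nx * ny,
         pixel_to_fiber = pixel_to_fiber,
         centroids = centroids, pixel_xy = pixel_xy),
    class = "sensor_layout"
  )
}
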