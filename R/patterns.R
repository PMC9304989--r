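#' Rectangular perturbation panel
#'
#' The plane underneath the phantom on which perturbation patterns live
#' (the micromirror display area for letter/circle patterns, or the plane
#' containing the flow tubes). Default physical size 10.6 x 13.9 mm,
#' discretized into cells of roughly 1/3 mm.
#'
#' @param nx,ny number of cells across width and height.
#' @param width,height physical panel size in mm.
#' @return An object of class `panel_grid` with cell-center coordinates
#'   `x`, `y` (length `nx * ny`, column-major with x varying slowest) and
#'   the panel dimensions.
#' @export
panel_grid <- function(nx = 32L, ny = 42L, width = 10.6, height = 13.9) {
  px <- seq(-width / 2, width / 2, length.out = nx)
  py <- seq(-height / 2, height / 2, length.out = ny)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         width = width, height = height,
         x = rep(px, each = ny), y = rep(py, times = nx)),
    class = "panel_grid"
  )
}

#' Parametric per-fiber sensitivity kernel
#'
#' A two-dimensional Gaussian weight field per detection fiber, centered
#' under the fiber's surface position with width `sigma` tied to half the
#' source-detector separation, normalized so each fiber's weights sum to
#' one over the panel. This is a parametric stand-in for a full photon
#' transport sensitivity map: it preserves the qualitative property that a
#' perturbation mostly affects the fibers above it, which is what drives
#' spatial classification.
#'
#' @param probe a [make_probe()] geometry.
#' @param grid a [panel_grid()].
#' @param sigma Gaussian width in mm (default `sd_separation / 2`).
#' @return A `n_cells x n_fibers` matrix of non-negative weights; each
#'   column sums to 1.
#' @export
sensitivity_kernel <- function(probe, grid, sigma = probe$sd_separation / 2) {
  stop_if_not_scalar_positive(sigma, "sigma")
  K <- vapply(seq_len(probe$n_fibers), function(p) {
    w <- exp(-((grid$x - probe$fiber_x[p])^2 +
                 (grid$y - probe$fiber_y[p])^2) / (2 * sigma^2))
    w / sum(w)
  }, numeric(length(grid$x)))
  structure(K, grid_nx = grid$nx, grid_ny = grid$ny)
}

# 16 x 16 binary glyph rasters for the built-in letter patterns.
# Strings are rows, top to bottom; '#' marks an on-mirror cell.
.glyph_rows <- list(
  D = c("##############  ", "############### ", "###          ###",
        "###           ##", "###           ##", "###           ##",
        "###           ##", "###           ##", "###           ##",
        "###           ##", "###           ##", "###           ##",
        "###           ##", "###          ###", "############### ",
        "##############  "),
  U = c("##            ##", "##            ##", "##            ##",
        "##            ##", "##            ##", "##            ##",
        "##            ##", "##            ##", "##            ##",
        "##            ##", "##            ##", "##            ##",
        "###          ###", " ####        ###", "  ############  ",
        "   ##########   "),
  K = c("##          ####", "##         #### ", "##        ####  ",
        "##       ####   ", "##      ####    ", "##     ####     ",
        "##    ####      ", "##  #####       ", "######          ",
        "##  #####       ", "##    ####      ", "##     ####     ",
        "##      ####    ", "##       ####   ", "##        ####  ",
        "##         #### "),
  E = c("################", "################", "##              ",
        "##              ", "##              ", "##              ",
        "################", "################", "##              ",
        "##              ", "##              ", "##              ",
        "##              ", "##              ", "################",
        "################")
)

.glyph_matrix <- function(letter) {
  rows <- .glyph_rows[[letter]]
  if (is.null(rows)) stop(sprintf("no built-in glyph for '%s'", letter))
  do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]] == "#")))
}

# Rasterize a 16x16 glyph onto panel cells with an affine placement.
.rasterize_glyph <- function(glyph, grid, shift = c(0, 0), rot = 0,
                             scale = 1, half_size = 4) {
  half <- half_size * scale
  cs <- cos(rot); sn <- sin(rot)
  X <- grid$x - shift[1]
  Y <- grid$y - shift[2]
  u <- (cs * X + sn * Y) / half
  v <- (-sn * X + cs * Y) / half
  i <- floor((v + 1) / 2 * 16)
  j <- floor((u + 1) / 2 * 16)
  m <- numeric(length(X))
  ok <- i >= 0 & i < 16 & j >= 0 & j < 16
  m[ok] <- glyph[cbind(16 - i[ok], j[ok] + 1)]
  m
}

.new_pattern <- function(kind, mask, grid, rate_scale, class_label,
                         flip_rate = NA_real_, tube_specs = NULL) {
  if (any(mask < 0 | mask > 1)) stop("mask values must lie in [0, 1]")
  structure(
    list(kind = kind, mask = mask, grid = grid, rate_scale = rate_scale,
         class_label = as.integer(class_label), flip_rate = flip_rate,
         tube_specs = tube_specs),
    class = "perturbation_pattern"
  )
}

# Decorrelation rate induced per kHz of mirror flip rate on a fully
# covered sensitivity kernel (s^-1 per kHz). The flip-to-decorrelation
# transfer is a modelling choice: rate scales linearly with flip rate, so
# 10 kHz induces twice the rate of 5 kHz.
.dmd_rate_per_khz <- 4000

#' Letter-shaped perturbation pattern
#'
#' A binary letter mask displayed on the panel, emulating a micromirror
#' display flipping at `flip_rate` Hz. Letters are generated from built-in
#' 16 x 16 glyph rasters; within-class variability comes from the affine
#' placement arguments (`shift`, `rot`, `scale`), which the dataset
#' generator randomizes per event.
#'
#' @param letter one of `"D"`, `"U"`, `"K"`, `"E"`.
#' @param grid a [panel_grid()].
#' @param flip_rate mirror flip rate in Hz (5000-10000).
#' @param shift panel-plane offset in mm (length 2).
#' @param rot rotation in radians.
#' @param scale relative glyph size.
#' @return A `perturbation_pattern` of kind `"letter"`.
#' @export
letter_pattern <- function(letter, grid = panel_grid(), flip_rate = 5000,
                           shift = c(0, 0), rot = 0, scale = 1) {
  letter <- match.arg(letter, names(.glyph_rows))
  mask <- .rasterize_glyph(.glyph_matrix(letter), grid, shift, rot, scale)
  .new_pattern("letter", mask, grid,
               rate_scale = .dmd_rate_per_khz * flip_rate / 1000,
               class_label = match(letter, names(.glyph_rows)),
               flip_rate = flip_rate)
}

#' Circle perturbation pattern (spatio-temporal classes)
#'
#' Two circles of class-dependent size displayed together on the panel at
#' a class-dependent flip rate; the four classes cross circle size
#' (small/large) with flip rate (5/10 kHz).
#'
#' @param class_label integer 1-4.
#' @param grid a [panel_grid()].
#' @param shift common center offset in mm (length 2), randomized per
#'   event by the dataset generator.
#' @return A `perturbation_pattern` of kind `"circles"`.
#' @export
circles_pattern <- function(class_label, grid = panel_grid(),
                            shift = c(0, 0)) {
  stopifnot(class_label %in% 1:4)
  small <- class_label %in% c(1L, 2L)
  flip <- if (class_label %in% c(1L, 3L)) 5000 else 10000
  r <- if (small) 1.4 else 2.8
  centers <- list(c(-2.6, 2.2), c(2.6, -2.2))
  mask <- numeric(length(grid$x))
  for (ct in centers) {
    d2 <- (grid$x - ct[1] - shift[1])^2 + (grid$y - ct[2] - shift[2])^2
    mask[d2 <= r^2] <- 1
  }
  .new_pattern("circles", mask, grid,
               rate_scale = .dmd_rate_per_khz * flip / 1000,
               class_label = class_label, flip_rate = flip)
}

# Decorrelation rate induced per mm/s of flow on a fully covered kernel
# (s^-1 per mm/s), and the depth attenuation length constant (mm).
.flow_rate_per_mms <- 3000
.depth_length_const <- 1.5
.flow_speed_ref <- 2 # mm/s; mask values are v / v_ref, capped at 1

#' Flow-tube perturbation pattern
#'
#' Two parallel tubes of scattering fluid under the panel; each tube's
#' flow speed sets the local decorrelation rate. The mask stores speed
#' relative to a 2 mm/s reference, and the tube depth attenuates the
#' perturbation exponentially with a 1.5 mm length constant, emulating the
#' loss of sensitivity to deeper perturbations.
#'
#' @param flow_speeds length-2 numeric, mm/s (one per tube).
#' @param grid a [panel_grid()].
#' @param depth tube depth below the phantom in mm (default 5).
#' @param diameter tube diameter in mm (default 3).
#' @param positions tube center x-positions in mm.
#' @param class_label integer ground-truth category.
#' @return A `perturbation_pattern` of kind `"tubes"`.
#' @export
tubes_pattern <- function(flow_speeds, grid = panel_grid(), depth = 5,
                          diameter = 3, positions = c(-3, 3),
                          class_label = 1L) {
  stopifnot(length(flow_speeds) == 2, all(flow_speeds >= 0),
            diameter > 0, depth > 0)
  mask <- numeric(length(grid$x))
  for (t in 1:2) {
    cells <- abs(grid$x - positions[t]) <= diameter / 2
    mask[cells] <- pmin(1, flow_speeds[t] / .flow_speed_ref)
  }
  rate_scale <- .flow_rate_per_mms * .flow_speed_ref *
    exp(-max(0, depth - 5) / .depth_length_const)
  .new_pattern("tubes", mask, grid, rate_scale = rate_scale,
               class_label = class_label,
               tube_specs = data.frame(
                 tube = 1:2, diameter = diameter,
                 flow_speed = flow_speeds, depth = depth,
                 position = positions))
}

#' Per-fiber effective decorrelation times under a perturbation
#'
#' Converts a perturbation pattern into each fiber's effective field
#' decorrelation time by adding the kernel-weighted perturbation rate to
#' the baseline rate of the medium:
#' `1 / tau_p = 1 / tau_c_baseline + s(tissue) * rate_scale *
#' sum_xy kernel_p(xy) * mask(xy)`.
#' The tissue sensitivity factor `s = mu_s_ref / mu_s_prime` (reference
#' 0.7 mm^-1) encodes that deep perturbations couple more weakly to the
#' surface signal as the overlying medium becomes more turbid.
#'
#' @param pattern a `perturbation_pattern`.
#' @param kernel a [sensitivity_kernel()] on the same panel grid.
#' @param tissue a [tissue_preset()].
#' @param rate_scale optional override of the pattern's perturbation rate
#'   scale (s^-1), e.g. for dose-response checks.
#' @return Numeric vector of per-fiber decorrelation times (s), strictly
#'   positive; equals `tau_c_baseline` everywhere for an all-zero mask.
#' @export
pattern_to_fiber_tau <- function(pattern, kernel, tissue,
                                 rate_scale = pattern$rate_scale) {
  if (length(pattern$mask) != nrow(kernel))
    stop("pattern and kernel are defined on different panel grids")
  sens <- 0.7 / tissue$mu_s_prime
  overlap <- as.numeric(crossprod(kernel, pattern$mask))
  rate <- 1 / tissue$tau_c_baseline + sens * rate_scale * overlap
  1 / rate
}
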