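#' Field autocorrelation models
#'
#' Normalized field (amplitude) autocorrelation `g1(tau)` of the scattered
#' light. Three models are supported:
#'
#' * `"exponential"`: `exp(-tau / tau_c)`, the single-rate model used by
#'   the event simulator (params: `tau_c`).
#' * `"stretched_exponential"`: `exp(-(tau / tau_c)^gamma)` with
#'   `0 < gamma <= 1` (params: `tau_c`, `gamma`).
#' * `"semi_infinite_cde"`: the semi-infinite solution of the correlation
#'   diffusion equation with extrapolated-zero boundary, the standard DCS
#'   model for Brownian scatterer dynamics (params: `rho` source-detector
#'   separation in mm, `mu_a`, `mu_s_prime` in mm^-1, `k0` optical
#'   wavenumber in the medium in mm^-1, `alpha_Db` the flow/Brownian
#'   diffusion index in mm^2/s, optional `Reff`, default 0.493).
#'
#' For the semi-infinite model,
#' `g1(tau) = G1(tau) / G1(0)` with
#' `G1(tau) = [exp(-K r1)/r1 - exp(-K rb)/rb]`,
#' `K(tau)^2 = 3 mu_a mu_s' + 6 mu_s'^2 k0^2 alpha_Db tau`,
#' `r1 = sqrt(rho^2 + z0^2)`, `rb = sqrt(rho^2 + (z0 + 2 zb)^2)`,
#' `z0 = 1/mu_s'` and `zb` the extrapolated boundary distance.
#'
#' @param tau lag(s) in seconds, non-negative.
#' @param model model name.
#' @param params named list of model parameters (see above).
#' @return `g1` values in `[0, 1]`, same length as `tau`; `g1(0) = 1` and
#'   the curve is monotone non-increasing for all supported models.
#' @examples
#' field_g1(0, "exponential", list(tau_c = 1e-3)) # 1
#' field_g1(1e-3, "exponential", list(tau_c = 1e-3)) # exp(-1)
#' @export
field_g1 <- function(tau, model = c("exponential", "stretched_exponential",
                                    "semi_infinite_cde"),
                     params = list(tau_c = 1e-3)) {
  model <- match.arg(model)
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau < 0))
    stop("`tau` must be non-negative and finite")
  switch(model,
    exponential = {
      stop_if_not_scalar_positive(params$tau_c, "params$tau_c")
      exp(-tau / params$tau_c)
    },
    stretched_exponential = {
      stop_if_not_scalar_positive(params$tau_c, "params$tau_c")
      gamma <- params$gamma %||% 0.5
      if (gamma <= 0 || gamma > 1) stop("`gamma` must lie in (0, 1]")
      exp(-(tau / params$tau_c)^gamma)
    },
    semi_infinite_cde = g1_semi_infinite(tau, params)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

g1_semi_infinite <- function(tau, params) {
  for (nm in c("rho", "mu_a", "mu_s_prime", "k0", "alpha_Db"))
    stop_if_not_scalar_positive(params[[nm]], paste0("params$", nm))
  rho <- params$rho
  mu_a <- params$mu_a
  musp <- params$mu_s_prime
  k0 <- params$k0
  aDb <- params$alpha_Db
  Reff <- params$Reff %||% 0.493
  z0 <- 1 / musp
  zb <- 2 * (1 + Reff) / (3 * musp * (1 - Reff))
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  Ktau <- sqrt(3 * mu_a * musp + 6 * musp^2 * k0^2 * aDb * tau)
  K0 <- sqrt(3 * mu_a * musp)
  G <- function(K) exp(-K * r1) / r1 - exp(-K * rb) / rb
  G(Ktau) / G(K0)
}

#' Decay-rate fit of an intensity autocorrelation curve
#'
#' Fits `g2(tau) = 1 + b * exp(-2 * tau / tau_fit)` by linear regression of
#' `log(g2 - 1)` on `tau` over lags where the excess is positive, giving a
#' robust single-number summary of how fast a fiber's speckle decorrelates.
#' Used by the self-consistency checks and the depth/flow diagnostics, not
#' by the clustering pipeline (which consumes whole curves).
#'
#' @param g2 numeric vector of autocorrelation values.
#' @param lags_s lag values in seconds.
#' @return list with `rate` (1/s, decay rate `2/tau_fit`), `tau_fit` (s)
#'   and `intercept` (fitted zero-lag excess).
#' @export
fit_g2_decay <- function(g2, lags_s) {
  stopifnot(length(g2) == length(lags_s))
  excess <- g2 - 1
  ok <- is.finite(excess) & excess > 0
  if (sum(ok) < 3) return(list(rate = NA_real_, tau_fit = NA_real_,
                               intercept = NA_real_))
  fit <- stats::lm.fit(cbind(1, lags_s[ok]), log(excess[ok]))
  rate <- -fit$coefficients[[2]]
  list(rate = rate, tau_fit = 2 / rate, intercept = exp(fit$coefficients[[1]]))
}
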