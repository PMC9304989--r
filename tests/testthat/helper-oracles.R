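# Independent reference implementations used to cross-check the package.
# Each is written directly from the defining formula, sharing no code with
# the implementations under test.

# Direct-sum intensity autocorrelation of one count vector.
oracle_g2 <- function(x, lag_bins, symmetric = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  vapply(lag_bins, function(L) {
    a <- x[1:(n - L)]
    b <- x[(1 + L):n]
    num <- mean(a * b)
    den <- if (symmetric) mean(a) * mean(b) else mean(x)^2
    if (den > 0) num / den else NA_real_
  }, numeric(1))
}

# Nearest-centroid assignment by explicit distance comparison.
# M is d x K; Z is N x d.
oracle_assign <- function(Z, M) {
  apply(Z, 1L, function(z) {
    d <- colSums((M - z)^2)
    which(d == min(d))[1L]
  })
}

# Matched accuracy by full enumeration of one-to-one label mappings
# (feasible for small K only).
oracle_matched_accuracy <- function(predicted, truth) {
  pl <- sort(unique(predicted))
  tl <- sort(unique(truth))
  k <- max(length(pl), length(tl))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    hits <- 0
    for (i in seq_along(pl)) {
      j <- p[i]
      if (j <= length(tl))
        hits <- hits + sum(predicted == pl[i] & truth == tl[j])
    }
    best <- max(best, hits)
  }
  best / length(truth)
}

# Semi-infinite correlation-diffusion field autocorrelation, written
# independently from the standard analytic solution.
oracle_cde_g1 <- function(tau, mu_a, mu_s_prime, alpha_Db,
                          rho = 9, lambda0 = 670e-6, n_tissue = 1.33,
                          Reff = 0.493) {
  k0 <- 2 * pi * n_tissue / lambda0
  z0 <- 1 / mu_s_prime
  zb <- (2 / 3) * (1 + Reff) / ((1 - Reff) * mu_s_prime)
  G <- function(tt) {
    K <- sqrt(3 * mu_a * mu_s_prime + 6 * mu_s_prime^2 * k0^2 * alpha_Db * tt)
    r1 <- sqrt(rho^2 + z0^2)
    rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
    exp(-K * r1) / r1 - exp(-K * rb) / rb
  }
  G(tau) / G(0)
}

# Shared fast fixture: one simulated event, cached per session.
fixture_event <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_event(tubes_pattern(c(0, 0)), make_probe(),
                               tissue_preset("tissue1"),
                               config = sim_config(seed = 42L),
                               duration = 0.05)
    }
    cache
  }
})
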