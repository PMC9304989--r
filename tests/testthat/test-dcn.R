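# Small synthetic feature set: three well-separated Gaussian blobs.
.blobs <- function(seed, n_per = 30L, d = 12L, sep = 6) {
  speckleclass:::with_seed(seed, {
    centers <- matrix(stats::rnorm(3 * d), 3, d) * sep
    X <- do.call(rbind, lapply(1:3, function(k)
      matrix(stats::rnorm(n_per * d, sd = 0.5), n_per, d) +
        matrix(centers[k, ], n_per, d, byrow = TRUE)))
    list(X = X, y = rep(1:3, each = n_per))
  })
}

.small_cfg <- function(d, seed = 1L, lambda = 0.5) {
  dcn_config(input_dim = d, K = 3L, latent_dim = 2L, lambda = lambda,
             encoder_widths = 16L, epochs_pretrain = 30L,
             epochs_joint = 15L, batch_size = 16L, seed = seed)
}

test_that("configuration validates its arguments", {
  expect_error(dcn_config(10, 1), "K")
  expect_error(dcn_config(10, 3, latent_dim = 0), "latent_dim")
  expect_error(dcn_config(10, 3, lambda = -1), "lambda")
  cfg <- .small_cfg(12L)
  expect_equal(speckleclass:::.dcn_widths(cfg), c(12L, 16L, 2L, 16L, 12L))
})

test_that("autoencoder pretraining reduces reconstruction loss deterministically", {
  b <- .blobs(1)
  cfg <- .small_cfg(ncol(b$X))
  st <- pretrain_autoencoder(b$X, cfg)
  expect_s3_class(st, "dcn_state")
  expect_lt(utils::tail(st$loss_trace$recon, 1), st$initial_recon)
  st2 <- pretrain_autoencoder(b$X, cfg)
  expect_identical(st$net$W, st2$net$W)
  expect_error(pretrain_autoencoder(cbind(b$X, NA), cfg), "finite")
})

test_that("k-means++ draws distinct data points as centroids", {
  b <- .blobs(2)
  M <- kmeanspp_init(b$X, 3L, seed = 77)
  expect_equal(dim(M), c(ncol(b$X), 3L))
  # each centroid is one of the data rows
  for (k in 1:3)
    expect_true(any(apply(b$X, 1, function(r) all(r == M[, k]))))
  expect_gt(min(dist(t(M))), 0)
  expect_identical(M, kmeanspp_init(b$X, 3L, seed = 77))
  expect_error(kmeanspp_init(b$X[1:2, ], 3L, 1), "at least K")
})

test_that("assignment step matches brute-force nearest centroid", {
  b <- .blobs(3)
  M <- kmeanspp_init(b$X, 3L, seed = 5)
  S <- assignment_step(b$X, M)
  expect_equal(S, unname(oracle_assign(b$X, M)))
})

test_that("centroid update takes cluster means and reseeds empty clusters", {
  Z <- matrix(c(0, 0, 1, 1, 10, 10, 12, 12), 4, 2, byrow = TRUE)
  S <- c(1L, 1L, 2L, 2L)
  M <- centroid_update(Z, S, K = 2L)
  expect_equal(M, cbind(c(0.5, 0.5), c(11, 11)))
  # cluster 3 is empty: reseeded at the point farthest from its old centroid
  M3 <- centroid_update(Z, S, K = 3L, prev_M = cbind(M, c(0, 0)))
  expect_equal(M3[, 3], c(12, 12))
  expect_equal(cluster_cost(Z, M, S), 0.5 + 0.5 + 2 + 2)
  # discrete steps never increase the cost
  S2 <- assignment_step(Z, M)
  expect_lte(cluster_cost(Z, M, S2), cluster_cost(Z, M, S))
})

test_that("joint training separates blobs and traces both loss terms", {
  b <- .blobs(4)
  fit <- dcn_fit(b$X, .small_cfg(ncol(b$X), seed = 4L), truth = b$y)
  expect_equal(fit$report$accuracy, 1)
  joint <- fit$state$loss_trace[fit$state$loss_trace$phase == "joint", ]
  expect_equal(nrow(joint), 15L)
  expect_true(all(is.finite(joint$cluster)))
  expect_equal(dim(fit$state$embedding), c(90L, 2L))
})

test_that("a zero clustering weight reproduces plain autoencoder training", {
  b <- .blobs(5)
  cfg <- .small_cfg(ncol(b$X), seed = 9L, lambda = 0)
  fit <- dcn_fit(b$X, cfg, truth = b$y)
  ae <- pretrain_autoencoder(b$X, cfg,
                             epochs = cfg$epochs_pretrain + cfg$epochs_joint)
  expect_identical(fit$state$net$W, ae$net$W)
  expect_identical(fit$state$net$b, ae$net$b)
})
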