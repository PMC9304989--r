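#' Deep clustering network configuration
#'
#' The network is a fully connected stacked autoencoder (encoder
#' `input -> encoder_widths -> latent_dim`, mirrored decoder) trained
#' jointly with a k-means clustering loss on the latent code:
#' `sum_i ||g(f(x_i)) - x_i||^2 + (lambda/2) ||f(x_i) - M s_i||^2`
#' with one-hot assignments `s_i` and centroid matrix `M`. Optimization
#' alternates between stochastic gradient steps on the network weights
#' (with `S`, `M` fixed) and discrete assignment/centroid updates.
#'
#' @param input_dim feature dimension (fibers x lags).
#' @param K number of clusters (>= 2).
#' @param latent_dim embedding dimension (default 8).
#' @param lambda clustering-loss weight (default 0.5); 0 decouples the
#'   objective into plain autoencoder training.
#' @param encoder_widths hidden-layer widths of the encoder, excluding
#'   the latent layer (default `c(256, 64)`).
#' @param epochs_pretrain,epochs_joint epoch counts (defaults 100 / 40).
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param lloyd_init_iters k-means refinement iterations after the
#'   k-means++ draw, before joint training (default 5).
#' @param seed integer seed; initialization, batch schedule and
#'   k-means++ draws use decoupled streams derived from it.
#' @return An object of class `dcn_config`.
#' @export
dcn_config <- function(input_dim, K, latent_dim = 8L, lambda = 0.5,
                       encoder_widths = c(256L, 64L),
                       epochs_pretrain = 100L, epochs_joint = 40L,
                       batch_size = 64L, learning_rate = 1e-3,
                       lloyd_init_iters = 5L, seed = 1L) {
  if (latent_dim < 1) stop("`latent_dim` must be >= 1")
  if (K < 2) stop("`K` must be >= 2")
  if (lambda < 0) stop("`lambda` must be >= 0")
  stop_if_not_scalar_positive(learning_rate, "learning_rate")
  structure(
    list(input_dim = as.integer(input_dim), K = as.integer(K),
         latent_dim = as.integer(latent_dim), lambda = lambda,
         encoder_widths = as.integer(encoder_widths),
         epochs_pretrain = as.integer(epochs_pretrain),
         epochs_joint = as.integer(epochs_joint),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         lloyd_init_iters = as.integer(lloyd_init_iters),
         seed = as.numeric(seed)),
    class = "dcn_config"
  )
}

# ---- network internals ------------------------------------------------

# widths: input, encoder hiddens, latent, mirrored decoder, input
.dcn_widths <- function(config) {
  enc <- c(config$input_dim, config$encoder_widths, config$latent_dim)
  c(enc, rev(enc)[-1])
}

# tanh on hidden layers; linear on the latent layer and the output layer
.dcn_acts <- function(config) {
  n_enc <- length(config$encoder_widths) + 1L
  n_dec <- n_enc
  acts <- c(rep("tanh", n_enc - 1L), "linear",
            rep("tanh", n_dec - 1L), "linear")
  acts
}

.dcn_init_net <- function(config) {
  widths <- .dcn_widths(config)
  nl <- length(widths) - 1L
  with_seed(derive_seed(config$seed, 11L), {
    W <- vector("list", nl); b <- vector("list", nl)
    for (l in seq_len(nl)) {
      lim <- sqrt(6 / (widths[l] + widths[l + 1L])) # Glorot uniform
      W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1L], -lim, lim),
                       widths[l], widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    list(W = W, b = b, acts = .dcn_acts(config),
         latent_layer = length(config$encoder_widths) + 1L)
  })
}

.dcn_forward <- function(net, X) {
  A <- vector("list", length(net$W) + 1L)
  A[[1L]] <- X
  for (l in seq_along(net$W)) {
    Z <- A[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    A[[l + 1L]] <- if (net$acts[l] == "tanh") tanh(Z) else Z
  }
  A
}

#' Encode features into the latent space
#'
#' @param state a `dcn_state` (or the `net` element of one).
#' @param X feature matrix.
#' @return N x latent_dim embedding matrix.
#' @export
dcn_encode <- function(state, X) {
  net <- if (!is.null(state$net)) state$net else state
  A <- X
  for (l in seq_len(net$latent_layer)) {
    Z <- sweep(A %*% net$W[[l]], 2L, net$b[[l]], `+`)
    A <- if (net$acts[l] == "tanh") tanh(Z) else Z
  }
  A
}

.adam_init <- function(net) {
  list(m_W = lapply(net$W, function(w) w * 0),
       v_W = lapply(net$W, function(w) w * 0),
       m_b = lapply(net$b, function(b) b * 0),
       v_b = lapply(net$b, function(b) b * 0),
       t = 0L)
}

# one Adam step given gradients; returns list(net, opt)
.adam_step <- function(net, opt, gW, gb, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$m_W[[l]] <- beta1 * opt$m_W[[l]] + (1 - beta1) * gW[[l]]
    opt$v_W[[l]] <- beta2 * opt$v_W[[l]] + (1 - beta2) * gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$m_W[[l]] / c1) / (sqrt(opt$v_W[[l]] / c2) + eps)
    opt$m_b[[l]] <- beta1 * opt$m_b[[l]] + (1 - beta1) * gb[[l]]
    opt$v_b[[l]] <- beta2 * opt$v_b[[l]] + (1 - beta2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$m_b[[l]] / c1) / (sqrt(opt$v_b[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

# backprop of recon loss (+ optional cluster pull at the latent layer)
# latent_target: NULL or N x latent matrix (M s_i rows); lambda weight
.dcn_grads <- function(net, X, lambda = 0, latent_target = NULL) {
  A <- .dcn_forward(net, X)
  nb <- nrow(X)
  nl <- length(net$W)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  # output delta: d/dXhat mean_i ||xhat - x||^2
  delta <- 2 * (A[[nl + 1L]] - X) / nb
  for (l in rev(seq_len(nl))) {
    if (net$acts[l] == "tanh") delta <- delta * (1 - A[[l + 1L]]^2)
    if (!is.null(latent_target) && lambda > 0 && l == net$latent_layer) {
      # inject d/dz (lambda/2) mean_i ||z_i - M s_i||^2 when passing the
      # latent layer on the way down
      delta <- delta + lambda * (A[[l + 1L]] - latent_target) / nb
    }
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- delta %*% t(net$W[[l]])
  }
  recon <- mean(rowSums((A[[nl + 1L]] - X)^2))
  list(gW = gW, gb = gb, recon = recon)
}

# The full batch schedule (pretrain + joint) is drawn up front from its
# own seed stream, so a lambda = 0 joint phase consumes exactly the same
# batches as continued autoencoder training.
.dcn_batches <- function(config, n) {
  total <- config$epochs_pretrain + config$epochs_joint
  with_seed(derive_seed(config$seed, 12L), {
    lapply(seq_len(total), function(e) {
      ord <- sample.int(n)
      split(ord, ceiling(seq_along(ord) / config$batch_size))
    })
  })
}

.mean_recon_loss <- function(net, X) {
  A <- .dcn_forward(net, X)
  mean(rowSums((A[[length(A)]] - X)^2))
}

#' Pretrain the stacked autoencoder
#'
#' End-to-end reconstruction training (no clustering term). Reproducible
#' per seed: identical configuration and data give bit-identical weights.
#'
#' @param features N x D feature matrix (finite).
#' @param config a [dcn_config()].
#' @param epochs number of epochs (default `config$epochs_pretrain`);
#'   pass `config$epochs_pretrain + config$epochs_joint` to reproduce the
#'   weight trajectory of [dcn_fit()] with `lambda = 0`.
#' @return A `dcn_state` with the trained `net`, the optimizer state and
#'   the per-epoch reconstruction `loss_trace` (no centroids yet).
#' @export
pretrain_autoencoder <- function(features, config, epochs = NULL) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("`features` must be finite")
  if (ncol(features) != config$input_dim)
    stop("feature dimension does not match `config$input_dim`")
  epochs <- epochs %||% config$epochs_pretrain
  net <- .dcn_init_net(config)
  opt <- .adam_init(net)
  batches <- .dcn_batches(config, nrow(features))
  trace <- data.frame(epoch = integer(), recon = numeric(),
                      cluster = numeric(), phase = character())
  loss0 <- .mean_recon_loss(net, features)
  for (e in seq_len(epochs)) {
    # epoch loss traced as the running mean of minibatch losses (one full
    # forward pass per epoch would double the training cost)
    bl <- 0; nb <- 0L
    for (idx in batches[[e]]) {
      g <- .dcn_grads(net, features[idx, , drop = FALSE])
      st <- .adam_step(net, opt, g$gW, g$gb, config$learning_rate)
      net <- st$net; opt <- st$opt
      bl <- bl + g$recon * length(idx); nb <- nb + length(idx)
    }
    trace <- rbind(trace, data.frame(epoch = e, recon = bl / nb,
                                     cluster = NA_real_, phase = "pretrain"))
  }
  structure(list(net = net, opt = opt, M = NULL, assignments = NULL,
                 loss_trace = trace, initial_recon = loss0,
                 config = config),
            class = "dcn_state")
}

#' k-means++ centroid initialization
#'
#' The first centroid is drawn uniformly from the points; each subsequent
#' centroid is drawn with probability proportional to the squared
#' distance to the nearest centroid chosen so far (the D^2 law).
#'
#' @param embedding N x d matrix.
#' @param K number of centroids (N >= K).
#' @param seed integer seed.
#' @return d x K centroid matrix.
#' @export
kmeanspp_init <- function(embedding, K, seed) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < K) stop("need at least K points")
  with_seed(seed, {
    idx <- integer(K)
    idx[1L] <- sample.int(n, 1L)
    if (K > 1L) {
      d2 <- rowSums((embedding - matrix(embedding[idx[1L], ], n,
                                        ncol(embedding), byrow = TRUE))^2)
      for (k in 2L:K) {
        if (all(d2 == 0)) {
          idx[k] <- sample.int(n, 1L)
        } else {
          idx[k] <- sample.int(n, 1L, prob = d2)
        }
        nd <- rowSums((embedding - matrix(embedding[idx[k], ], n,
                                          ncol(embedding), byrow = TRUE))^2)
        d2 <- pmin(d2, nd)
      }
    }
    t(embedding[idx, , drop = FALSE])
  })
}

#' Assign points to nearest centroids
#'
#' Squared Euclidean distance; ties go to the lowest centroid index. For
#' fixed embeddings and centroids this step can only decrease the
#' clustering cost.
#'
#' @param embedding N x d matrix (non-empty).
#' @param M d x K centroid matrix.
#' @return Integer vector of cluster indices in `1..K` (the one-hot
#'   assignments in index form).
#' @export
assignment_step <- function(embedding, M) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) == 0L) stop("empty embedding")
  D <- outer(rowSums(embedding^2), rep(1, ncol(M))) -
    2 * embedding %*% M + outer(rep(1, nrow(embedding)), colSums(M^2))
  max.col(-D, ties.method = "first")
}

#' Update centroids from assignments
#'
#' Each non-empty cluster's centroid becomes the mean of its points; an
#' empty cluster is reseeded at the point farthest from its previous
#' centroid (keeping K fixed). For fixed assignments the mean update can
#' only decrease the clustering cost; reseeding is then cost-neutral for
#' the existing assignments.
#'
#' @param embedding N x d matrix.
#' @param assignments integer vector in `1..K`.
#' @param K number of clusters.
#' @param prev_M previous d x K centroid matrix (for reseeding).
#' @return d x K centroid matrix.
#' @export
centroid_update <- function(embedding, assignments, K = max(assignments),
                            prev_M = NULL) {
  embedding <- as.matrix(embedding)
  d <- ncol(embedding)
  M <- matrix(NA_real_, d, K)
  for (k in seq_len(K)) {
    pts <- embedding[assignments == k, , drop = FALSE]
    if (nrow(pts) > 0L) {
      M[, k] <- colMeans(pts)
    } else if (!is.null(prev_M)) {
      far <- which.max(rowSums((embedding -
        matrix(prev_M[, k], nrow(embedding), d, byrow = TRUE))^2))
      M[, k] <- embedding[far, ]
    } else {
      M[, k] <- embedding[1L, ]
    }
  }
  M
}

#' Clustering cost
#'
#' Total squared distance between embedded points and their assigned
#' centroids, `sum_i ||z_i - M s_i||^2`.
#'
#' @inheritParams centroid_update
#' @param M d x K centroid matrix.
#' @return Non-negative scalar.
#' @export
cluster_cost <- function(embedding, M, assignments) {
  sum((as.matrix(embedding) - t(M)[assignments, , drop = FALSE])^2)
}

#' Fit the deep clustering network
#'
#' Runs autoencoder pretraining, k-means++ initialization in the latent
#' space (plus a few Lloyd refinements), then alternates between (a)
#' minibatch gradient steps on the joint objective with assignments and
#' centroids fixed, (b) the assignment step, and (c) the centroid update.
#' Both loss terms are recorded per epoch, and the discrete steps are
#' checked to never increase the clustering cost for the current
#' embedding. With `lambda = 0` the weight trajectory is identical to
#' continued autoencoder training under the same seed.
#'
#' @param features N x D finite feature matrix.
#' @param config a [dcn_config()]; `N >= K` required.
#' @param truth optional ground-truth labels; if given, the returned
#'   report includes permutation-matched accuracy and a confusion matrix.
#' @return A list with `state` (class `dcn_state`: network, centroids
#'   `M`, `assignments`, `loss_trace`) and `report` (a [cluster_report()]).
#' @export
dcn_fit <- function(features, config, truth = NULL) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("`features` must be finite")
  if (nrow(features) < config$K) stop("need at least K data points")
  state <- pretrain_autoencoder(features, config)
  net <- state$net; opt <- state$opt
  batches <- .dcn_batches(config, nrow(features))
  trace <- state$loss_trace

  Z <- dcn_encode(net, features)
  M <- kmeanspp_init(Z, config$K, derive_seed(config$seed, 13L))
  S <- assignment_step(Z, M)
  for (i in seq_len(config$lloyd_init_iters)) {
    M <- centroid_update(Z, S, config$K, M)
    S <- assignment_step(Z, M)
  }

  for (e in seq_len(config$epochs_joint)) {
    sched <- batches[[config$epochs_pretrain + e]]
    for (idx in sched) {
      Xb <- features[idx, , drop = FALSE]
      target <- if (config$lambda > 0) t(M)[S[idx], , drop = FALSE] else NULL
      g <- .dcn_grads(net, Xb, config$lambda, target)
      st <- .adam_step(net, opt, g$gW, g$gb, config$learning_rate)
      net <- st$net; opt <- st$opt
    }
    Z <- dcn_encode(net, features)
    cost_prev <- cluster_cost(Z, M, S)
    S <- assignment_step(Z, M)
    cost_assigned <- cluster_cost(Z, M, S)
    M <- centroid_update(Z, S, config$K, M)
    cost_updated <- cluster_cost(Z, M, S)
    if (cost_assigned > cost_prev + 1e-8 * (1 + cost_prev) ||
        cost_updated > cost_assigned + 1e-8 * (1 + cost_assigned))
      stop("clustering cost increased in a discrete update step")
    recon <- .mean_recon_loss(net, features)
    if (!is.finite(recon)) stop("training diverged: non-finite loss")
    trace <- rbind(trace, data.frame(
      epoch = config$epochs_pretrain + e, recon = recon,
      cluster = cost_updated, phase = "joint"))
  }
  state <- structure(
    list(net = net, opt = opt, M = M, assignments = S,
         loss_trace = trace, initial_recon = state$initial_recon,
         embedding = Z, config = config),
    class = "dcn_state")
  list(state = state,
       report = cluster_report(S, truth, embedding = Z))
}

#' @export
print.dcn_state <- function(x, ...) {
  cat(sprintf("<dcn_state> widths %s, lambda = %g, %d epochs traced\n",
              paste(.dcn_widths(x$config), collapse = "-"),
              x$config$lambda, nrow(x$loss_trace)))
  invisible(x)
}
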