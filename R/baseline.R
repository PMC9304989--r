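#' Classical dimension-reduction baselines
#'
#' Embeds the feature rows into two dimensions with a classical method
#' and clusters the embedding with k-means, providing the comparator for
#' the deep clustering network under the same matched-accuracy metric.
#'
#' * `"tsne_like"`: an exact (O(N^2)) t-distributed stochastic neighbor
#'   embedding implemented in-package: Gaussian input affinities with
#'   per-point bandwidths calibrated to a target perplexity, Student-t
#'   output kernel, gradient descent with momentum and early
#'   exaggeration.
#' * `"pca"`: first two principal components.
#'
#' @param features N x D matrix.
#' @param method `"tsne_like"` or `"pca"`.
#' @param seed integer seed (embedding initialization and k-means).
#' @param K number of clusters for the k-means stage (default 2).
#' @param perplexity t-SNE perplexity (default `min(30, (N - 1) / 3)`).
#' @param max_iter t-SNE gradient iterations (default 400).
#' @return A list with `embedding` (N x 2), `labels` (k-means cluster
#'   indices) and `method`.
#' @export
baseline_embed <- function(features, method = c("tsne_like", "pca"),
                           seed = 1L, K = 2L, perplexity = NULL,
                           max_iter = 400L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  emb <- switch(method,
    pca = {
      pr <- stats::prcomp(features, center = TRUE, scale. = FALSE)
      pr$x[, 1:2, drop = FALSE]
    },
    tsne_like = .tsne_exact(features, seed = derive_seed(seed, 21L),
                            perplexity = perplexity, max_iter = max_iter)
  )
  km <- with_seed(derive_seed(seed, 22L),
                  stats::kmeans(emb, centers = K, nstart = 10L,
                                iter.max = 50L))
  list(embedding = emb, labels = km$cluster, method = method)
}

# Exact t-SNE. Affinities from squared distances on (up to) the first 50
# principal components; binary search of per-point bandwidth to match
# log(perplexity) entropy; symmetrized P; early exaggeration x4 for the
# first quarter of the iterations; momentum 0.5 then 0.8.
.tsne_exact <- function(X, seed, perplexity = NULL, max_iter = 400L,
                        dims = 2L, eta = 100) {
  n <- nrow(X)
  perplexity <- perplexity %||% min(30, (n - 1) / 3)
  if (perplexity < 2) perplexity <- 2
  if (ncol(X) > 50L) {
    X <- stats::prcomp(X, center = TRUE)$x[, 1:50, drop = FALSE]
  }
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  Y <- with_seed(seed, matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  dY <- matrix(0, n, dims)
  exag_until <- max_iter %/% 4L
  Pe <- P * 4
  for (it in seq_len(max_iter)) {
    Puse <- if (it <= exag_until) Pe else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < 100L) 0.5 else 0.8
    dY <- mom * dY - eta * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
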