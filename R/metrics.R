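#' Permutation-matched clustering accuracy
#'
#' Accuracy of unlabeled cluster assignments after mapping predicted
#' cluster indices one-to-one onto true classes. The default maximizes
#' total agreement over all one-to-one mappings (optimal assignment,
#' solved exactly by dynamic programming over class subsets);
#' `method = "majority"` instead maps each predicted cluster to its
#' majority true class (not necessarily one-to-one).
#'
#' @param predicted integer-like cluster labels.
#' @param truth integer-like true class labels, same length.
#' @param method `"optimal"` (default) or `"majority"`.
#' @return Accuracy in `[0, 1]`.
#' @export
matched_accuracy <- function(predicted, truth, method = c("optimal",
                                                          "majority")) {
  method <- match.arg(method)
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have equal length")
  if (length(truth) == 0L) stop("empty label vectors")
  pl <- sort(unique(predicted))
  tl <- sort(unique(truth))
  C <- table(factor(predicted, levels = pl), factor(truth, levels = tl))
  if (method == "majority")
    return(sum(apply(C, 1L, max)) / length(truth))
  # pad to square so unmatched labels contribute zero
  k <- max(length(pl), length(tl))
  M <- matrix(0, k, k)
  M[seq_along(pl), seq_along(tl)] <- C
  best_assignment_sum(M) / length(truth)
}

# Maximum-sum one-to-one assignment by DP over column subsets, O(2^k k).
best_assignment_sum <- function(M) {
  k <- nrow(M)
  if (k > 20L) stop("assignment matching supports up to 20 classes")
  dp <- rep(-Inf, 2^k)
  dp[1L] <- 0
  popcount <- vapply(0:(2^k - 1), function(m) sum(bitwAnd(m, 2^(0:(k - 1))) > 0),
                     numeric(1))
  for (mask in 1:(2^k - 1)) {
    i <- popcount[mask + 1L] # row index to place (1-based)
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0) {
        cand <- dp[mask - bit + 1L] + M[i, j]
        if (cand > dp[mask + 1L]) dp[mask + 1L] <- cand
      }
    }
  }
  dp[2^k]
}

#' Chance-level accuracy of a K-way classification
#'
#' @param K number of categories (>= 1).
#' @return `1 / K`.
#' @examples
#' chance_baseline(4) # 0.25
#' chance_baseline(9) # 0.111...
#' @export
chance_baseline <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("`K` must be >= 1")
  1 / K
}

#' Clustering evaluation report
#'
#' @param predicted cluster labels.
#' @param truth optional true labels.
#' @param embedding optional embedding coordinates for plotting.
#' @return An object of class `cluster_report` with `predicted`,
#'   `accuracy` (matched; `NA` without truth), `confusion` (rows =
#'   matched predicted clusters, columns = true classes) and `embedding`.
#' @export
cluster_report <- function(predicted, truth = NULL, embedding = NULL) {
  acc <- NA_real_
  confusion <- NULL
  if (!is.null(truth)) {
    acc <- matched_accuracy(predicted, truth)
    tl <- sort(unique(truth))
    mapped <- match_clusters(predicted, truth)
    confusion <- table(factor(mapped, levels = tl),
                       factor(truth, levels = tl))
  }
  structure(list(predicted = predicted, accuracy = acc,
                 confusion = confusion, embedding = embedding,
                 truth = truth),
            class = "cluster_report")
}

#' Relabel predicted clusters by the optimal matching
#'
#' @inheritParams matched_accuracy
#' @return `predicted` relabeled into the true-class label set where the
#'   optimal one-to-one matching maps them; unmatched clusters keep a
#'   label outside the true set.
#' @export
match_clusters <- function(predicted, truth) {
  pl <- sort(unique(predicted))
  tl <- sort(unique(truth))
  C <- table(factor(predicted, levels = pl), factor(truth, levels = tl))
  k <- max(length(pl), length(tl))
  M <- matrix(0, k, k)
  M[seq_along(pl), seq_along(tl)] <- C
  # recover the argmax assignment by DP + backtracking
  perm <- best_assignment_perm(M)
  map <- stats::setNames(rep(NA, length(pl)), pl)
  for (i in seq_along(pl)) {
    j <- perm[i]
    map[i] <- if (j <= length(tl)) tl[j] else NA
  }
  out <- map[as.character(predicted)]
  ifelse(is.na(out), -as.numeric(factor(predicted)), out)
}

best_assignment_perm <- function(M) {
  k <- nrow(M)
  dp <- rep(-Inf, 2^k)
  choice <- matrix(NA_integer_, 2^k, 1)
  dp[1L] <- 0
  popcount <- vapply(0:(2^k - 1), function(m) sum(bitwAnd(m, 2^(0:(k - 1))) > 0),
                     numeric(1))
  for (mask in 1:(2^k - 1)) {
    i <- popcount[mask + 1L]
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0) {
        cand <- dp[mask - bit + 1L] + M[i, j]
        if (cand > dp[mask + 1L]) {
          dp[mask + 1L] <- cand
          choice[mask + 1L, 1L] <- j
        }
      }
    }
  }
  perm <- integer(k)
  mask <- 2^k - 1
  for (i in rev(seq_len(k))) {
    j <- choice[mask + 1L, 1L]
    perm[i] <- j
    mask <- mask - bitwShiftL(1L, j - 1L)
  }
  perm
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> N = %d, matched accuracy = %s\n",
              length(x$predicted),
              ifelse(is.na(x$accuracy), "NA", sprintf("%.2f", x$accuracy))))
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}
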