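#' Build a bag-of-words dictionary of visual words
#'
#' Clusters SIFT descriptors with K-means and keeps the K centroids as visual
#' words. Initialization is k-means++ under the given seed, followed by Lloyd
#' iterations (convergence when the largest centroid shift falls below `tol`,
#' capped at `iter_max` iterations); a cluster that empties is re-seeded from
#' the point currently farthest from its assigned centroid. For large feature
#' collections, at most `max_fit` descriptors (a seeded subsample) enter the
#' clustering; dictionary quality is insensitive to this and fitting cost is
#' not.
#'
#' @param features A `sift_features` object or an n x 128 descriptor matrix.
#' @param K Number of visual words (default 400).
#' @param seed Integer seed controlling initialization and subsampling.
#' @param iter_max,tol Lloyd iteration cap and centroid-shift tolerance.
#' @param max_fit Maximum number of descriptors used to fit the clustering.
#' @return An object of class `bow_dictionary` with `words` (K x 128 matrix),
#'   `K` and `seed`.
#' @export
build_dictionary <- function(features, K = 400L, seed = 1L,
                             iter_max = 300L, tol = 1e-4,
                             max_fit = 20000L) {
  x <- if (inherits(features, "sift_features")) features$descriptors else features
  if (!is.matrix(x)) .stop_input("features must be a matrix or sift_features")
  K <- as.integer(K)
  if (K < 1L) .stop_input("K must be >= 1")
  if (nrow(x) < K) {
    .stop_input("need at least K = %d features, got %d", K, nrow(x))
  }
  withr::with_seed(as.integer(seed), {
    if (nrow(x) > max_fit) {
      x <- x[sample.int(nrow(x), max_fit), , drop = FALSE]
    }
    centers <- .kmeanspp_init(x, K)
    words <- .lloyd(x, centers, iter_max = iter_max, tol = tol)
  })
  structure(
    list(words = words, K = K, seed = as.integer(seed)),
    class = "bow_dictionary"
  )
}

#' @export
print.bow_dictionary <- function(x, ...) {
  cat(sprintf(
    "<bow_dictionary: %d visual words of length %d (seed %d)>\n",
    x$K, ncol(x$words), x$seed
  ))
  invisible(x)
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
.kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (K == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (k in 2:K) {
    if (all(d2 <= 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[k, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[k, ])^2))
  }
  centers
}

# Nearest-center assignment via the expansion |x - c|^2 = |x|^2 - 2 x.c + |c|^2
# (|x|^2 is constant per row, so argmax of x.c - |c|^2/2); ties -> lowest index.
.nearest_center <- function(x, centers, chunk = 20000L) {
  half <- rowSums(centers^2) / 2
  n <- nrow(x)
  out <- integer(n)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    scores <- x[s:e, , drop = FALSE] %*% t(centers)
    scores <- sweep(scores, 2L, half)
    out[s:e] <- max.col(scores, ties.method = "first")
  }
  out
}

.lloyd <- function(x, centers, iter_max = 300L, tol = 1e-4) {
  for (it in seq_len(iter_max)) {
    assign <- .nearest_center(x, centers)
    sums <- rowsum(x, assign)
    counts <- tabulate(assign, nbins = nrow(centers))
    new_centers <- centers
    present <- as.integer(rownames(sums))
    new_centers[present, ] <- sums / counts[present]
    empty <- which(counts == 0L)
    if (length(empty) > 0L) {
      # re-seed each empty cluster from the point farthest from its centroid
      d2 <- rowSums((x - new_centers[assign, , drop = FALSE])^2)
      for (k in empty) {
        far <- which.max(d2)
        new_centers[k, ] <- x[far, ]
        d2[far] <- 0
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  centers
}

#' Assign features to their nearest visual word
#'
#' Vector quantization: each descriptor is assigned to the Euclidean-nearest
#' visual word, ties broken by the lowest word index.
#'
#' @param features A `sift_features` object or descriptor matrix.
#' @param dictionary A [build_dictionary()] result.
#' @return An integer vector of 1-based word indices (one per feature).
#' @export
vq_assign <- function(features, dictionary) {
  x <- if (inherits(features, "sift_features")) features$descriptors else features
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(dictionary$words)) {
    .stop_input(
      "descriptor length %d does not match dictionary word length %d",
      ncol(x), ncol(dictionary$words)
    )
  }
  if (nrow(x) == 0L) return(integer(0))
  .nearest_center(x, dictionary$words)
}

#' Attach word assignments to a feature set
#'
#' Convenience wrapper storing [vq_assign()] output in the `words` field of a
#' `sift_features` object (required by the voting stage).
#'
#' @inheritParams vq_assign
#' @return The `sift_features` object with `words` filled in.
#' @export
assign_words <- function(features, dictionary) {
  stopifnot(inherits(features, "sift_features"))
  features$words <- vq_assign(features, dictionary)
  features
}

#' Bag-of-words histogram of a feature set
#'
#' Counts, for each visual word, the features assigned to it by vector
#' quantization. The counts sum to the number of features.
#'
#' @inheritParams vq_assign
#' @return An integer vector of length K.
#' @export
vq_histogram <- function(features, dictionary) {
  x <- if (inherits(features, "sift_features")) features$descriptors else features
  if (nrow(x) == 0L) return(integer(dictionary$K))
  tabulate(vq_assign(features, dictionary), nbins = dictionary$K)
}

#' Within-class similarity of the query histograms
#'
#' For each visual word k, averages `min(h_Qm(k), h_Ql(k))` over all ordered
#' pairs of distinct query patches (m != l), i.e. divides the double sum by
#' M(M-1). A large value means the word occurs consistently across query
#' patches.
#'
#' @param query_histograms An M x K matrix of bag-of-words counts (M >= 2).
#' @return A numeric vector `alpha` of length K.
#' @export
within_class_similarity <- function(query_histograms) {
  h <- .as_hist_matrix(query_histograms)
  m <- nrow(h)
  if (m < 2L) .stop_input("need at least 2 query histograms, got %d", m)
  acc <- numeric(ncol(h))
  for (i in seq_len(m)) {
    acc <- acc + colSums(pmin(matrix(h[i, ], m, ncol(h), byrow = TRUE), h))
  }
  # the i == l terms added min(h_i, h_i) = h_i; remove them
  acc <- acc - colSums(h)
  acc / (m * (m - 1))
}

#' Between-class similarity of query and background histograms
#'
#' For each visual word k, averages `min(h_Qm(k), h_Bn(k))` over all M x N
#' query/background patch pairs. A large value means the word is shared with
#' background patterns and so carries little discriminative information.
#'
#' @param query_histograms M x K matrix of counts (M >= 1).
#' @param background_histograms N x K matrix of counts (N >= 1).
#' @return A numeric vector `delta` of length K.
#' @export
between_class_similarity <- function(query_histograms, background_histograms) {
  hq <- .as_hist_matrix(query_histograms)
  hb <- .as_hist_matrix(background_histograms)
  if (nrow(hq) < 1L || nrow(hb) < 1L) {
    .stop_input("both histogram sets must be non-empty")
  }
  if (ncol(hq) != ncol(hb)) .stop_input("histogram lengths differ")
  acc <- numeric(ncol(hq))
  for (i in seq_len(nrow(hq))) {
    acc <- acc + colSums(pmin(matrix(hq[i, ], nrow(hb), ncol(hb), byrow = TRUE), hb))
  }
  acc / (nrow(hq) * nrow(hb))
}

#' Discriminative capability of each visual word
#'
#' The ratio of within-class to between-class similarity,
#' `d(k) = alpha(k) / (delta(k) + eps)`, with a small `eps` regularizing the
#' (otherwise undefined) zero-denominator case. Words with large `d` are both
#' representative of endosome patches and rare in background patches; `d` is
#' the vote weight in the localization stage.
#'
#' @param alpha,delta Non-negative vectors of equal length K.
#' @param eps Denominator regularizer (default 1e-12).
#' @return A numeric vector `d` of length K.
#' @export
discriminative_capability <- function(alpha, delta, eps = 1e-12) {
  if (length(alpha) != length(delta)) .stop_input("alpha and delta lengths differ")
  if (any(alpha < 0) || any(delta < 0)) {
    .stop_input("similarities must be non-negative")
  }
  alpha / (delta + eps)
}

#' Compute all discriminative weights from training histograms
#'
#' Bundles [within_class_similarity()], [between_class_similarity()] and
#' [discriminative_capability()] into one container. Here the denominator
#' regularizer defaults to `1/N` (N background patches): a word absent from
#' every background patch is weighted as if a single background occurrence
#' existed. A vanishing regularizer would let any such word outweigh all
#' finite-ratio words by many orders of magnitude, reducing the voting map to
#' single-word voting; `1/N` keeps the weights commensurate while preserving
#' their ordering.
#'
#' @inheritParams between_class_similarity
#' @param eps Denominator regularizer; `NULL` (default) uses `1/N`.
#' @return An object of class `discriminative_weights` with fields `alpha`,
#'   `delta` and `d`.
#' @export
discriminative_weights <- function(query_histograms, background_histograms,
                                   eps = NULL) {
  alpha <- within_class_similarity(query_histograms)
  delta <- between_class_similarity(query_histograms, background_histograms)
  if (is.null(eps)) {
    eps <- 1 / nrow(.as_hist_matrix(background_histograms))
  }
  structure(
    list(alpha = alpha, delta = delta,
         d = discriminative_capability(alpha, delta, eps)),
    class = "discriminative_weights"
  )
}

.as_hist_matrix <- function(h) {
  if (is.list(h) && !is.data.frame(h)) h <- do.call(rbind, h)
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  if (any(h < 0)) .stop_input("histogram counts must be non-negative")
  h
}
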