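# Training-fold oversampling: SMOTE class balancing and Gaussian-noise
# replication. Both operate on sample rows in the (selected) feature space
# and are only ever applied to training partitions; the cross-validation
# driver enforces this.

#' SMOTE: synthetic minority oversampling
#'
#' Balances a two-class sample by interpolating new minority points: each
#' synthetic point is a convex combination of a minority point and one of
#' its `k_neighbors` nearest minority neighbours (Euclidean distance), with
#' a uniform interpolation gap. Originals are preserved; synthesis stops
#' when the class counts are exactly equal.
#'
#' @param X numeric matrix, samples x features.
#' @param y 0/1 labels.
#' @param k_neighbors number of minority neighbours to draw from
#'   (default 5); reduced with a warning when the minority class is too
#'   small.
#' @param seed optional RNG seed.
#' @return List with balanced `X` and `y` (originals first, synthetic rows
#'   appended).
#' @export
smote <- function(X, y, k_neighbors = 5L, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (!is.null(seed)) set.seed(seed)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(list(X = X, y = y))
  minority <- if (n1 < n0) 1 else 0
  mi <- which(y == minority)
  n_min <- length(mi)
  if (n_min < 2) stop("minority class must have at least 2 samples")
  need <- abs(n0 - n1)
  k <- k_neighbors
  if (n_min - 1 < k) {
    k <- n_min - 1L
    warning("k_neighbors reduced to ", k, " (minority size ", n_min, ")")
  }
  M <- X[mi, , drop = FALSE]
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  nn <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn <- matrix(nn, nrow = k)  # k x n_min
  base <- sample.int(n_min, need, replace = TRUE)
  pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], 1L)
  gap <- runif(need)
  synth <- M[base, , drop = FALSE] +
    gap * (M[pick, , drop = FALSE] - M[base, , drop = FALSE])
  list(X = rbind(X, synth),
       y = c(y, rep(minority, need)))
}

#' Gaussian-noise sample replication
#'
#' Appends `factor` noisy copies of the sample: each copy is the original
#' rows plus independent Gaussian noise with diagonal covariance equal to
#' `scale` times the per-feature variance of `X` (default 1/100). Constant
#' features are replicated unchanged.
#'
#' @param X numeric matrix, samples x features.
#' @param factor number of noisy copies appended (default 9, i.e. a
#'   nine-times-larger set of new data on top of the original).
#' @param scale variance multiplier for the noise (default 1/100).
#' @param seed optional RNG seed.
#' @return Matrix with `(1 + factor) * nrow(X)` rows (originals first).
#' @export
gaussian_augment <- function(X, factor = 9L, scale = 1 / 100, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, factor >= 0, scale > 0)
  if (factor == 0) return(X)
  if (!is.null(seed)) set.seed(seed)
  sds <- sqrt(scale * apply(X, 2, stats::var))
  n <- nrow(X); p <- ncol(X)
  reps <- vector("list", factor)
  for (r in seq_len(factor)) {
    noise <- matrix(rnorm(n * p), n, p) * rep(sds, each = n)
    reps[[r]] <- X + noise
  }
  do.call(rbind, c(list(X), reps))
}
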