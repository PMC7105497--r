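#' Microstate discretization by k-means
#'
#' Lloyd iterations from k-means++ seeding, run until the summed center
#' shift drops below `tol` or `max_iter` is reached. The within-cluster
#' sum of squares is non-increasing across iterations. A cluster that
#' empties is reseeded to the point farthest from its nearest center, so
#' the requested `k` (e.g. the structural 500 or 2000 microstate counts)
#' is always preserved.
#'
#' @param F frames x features numeric matrix.
#' @param k number of microstates (<= number of frames).
#' @param seed integer seed (controls seeding; the result is then
#'   deterministic).
#' @param max_iter iteration cap (default 300).
#' @param tol convergence threshold on the maximum center displacement
#'   (default 1e-6).
#' @return A list of class `"discretization"`: `centers` (k x features),
#'   `labels` (per frame, 1-based), `inertia`, `k`, `seed`, `iterations`.
#' @export
kmeans_discretize <- function(F, k, seed = NULL, max_iter = 300L,
                              tol = 1e-6) {
  F <- as.matrix(F)
  n <- nrow(F)
  if (k > n) stop("k = ", k, " exceeds the number of frames ", n)
  if (k < 1) stop("k must be >= 1")
  centers <- with_seed(seed, function() kmeanspp_centers(F, k))
  f2 <- rowSums(F^2)
  it <- 0L
  inertia_trace <- numeric(0)
  repeat {
    it <- it + 1L
    d2 <- dist2_to_centers(F, centers, f2)
    labels <- max.col(-d2, ties.method = "first")
    inertia_trace[it] <- sum(d2[cbind(seq_len(n), labels)])
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(F[members, , drop = FALSE])
      } else {
        # empty-cluster repair: reseed to the farthest point
        dmin <- d2[cbind(seq_len(n), labels)]
        new_centers[j, ] <- F[which.max(dmin), ]
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol || it >= max_iter) break
  }
  d2 <- dist2_to_centers(F, centers, f2)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(pmax(d2[cbind(seq_len(n), labels)], 0))
  structure(list(centers = centers, labels = labels, inertia = inertia,
                 k = k, seed = seed, iterations = it,
                 inertia_trace = inertia_trace,
                 tol = tol, max_iter = max_iter),
            class = "discretization")
}

#' @export
print.discretization <- function(x, ...) {
  cat("<discretization> k =", x$k, " inertia =", format(x$inertia, digits = 6),
      " iterations =", x$iterations, "\n")
  invisible(x)
}

# k-means++ seeding on the rows of F using the current RNG stream.
kmeanspp_centers <- function(F, k) {
  n <- nrow(F)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    f2 <- rowSums(F^2)
    dmin <- rep(Inf, n)
    for (j in 2:k) {
      ci <- F[idx[j - 1L], ]
      d <- f2 + sum(ci^2) - 2 * drop(F %*% ci)
      dmin <- pmin(dmin, pmax(d, 0))
      idx[j] <- if (sum(dmin) > 0) sample.int(n, 1L, prob = dmin)
                else sample(setdiff(seq_len(n), idx[1:(j - 1L)]), 1L)
    }
  }
  F[idx, , drop = FALSE]
}

# Squared Euclidean distances of every row of F to every center.
dist2_to_centers <- function(F, centers, f2 = rowSums(F^2)) {
  d2 <- outer(f2, rowSums(centers^2), `+`) - 2 * tcrossprod(F, centers)
  pmax(d2, 0)
}

#' Assign frames to the nearest cluster centers
#'
#' Euclidean nearest-center labels; exact ties are broken toward the lowest
#' center index.
#'
#' @param F frames x features matrix (dimensionality must match the
#'   centers).
#' @param centers `k x features` center matrix, or a `"discretization"`.
#' @return Integer label vector (1-based).
#' @export
assign_frames <- function(F, centers) {
  if (inherits(centers, "discretization")) centers <- centers$centers
  F <- as.matrix(F); centers <- as.matrix(centers)
  if (ncol(F) != ncol(centers)) {
    stop("feature dimensionality (", ncol(F),
         ") does not match the centers (", ncol(centers), ")")
  }
  d2 <- dist2_to_centers(F, centers)
  max.col(-d2, ties.method = "first")
}
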