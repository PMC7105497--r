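# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Horn's quaternion method for the minimized RMSD: the optimal proper
# rotation corresponds to the largest eigenvalue of the 4x4 key matrix.
quat_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Xc, Yc)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(Xc^2) + sum(Yc^2) - 2 * lmax) / n, 0))
}

# Exhaustive double-loop minimum inter-set distance.
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
  }
  best
}

# Exhaustive nearest-center assignment (lowest index wins ties).
brute_assign <- function(F, centers) {
  apply(F, 1, function(x) {
    d <- apply(centers, 1, function(c) sum((x - c)^2))
    which.min(d)
  })
}

# Random proper rotation from the current RNG stream.
rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

# Multinomial log-likelihood of a transition matrix given counts.
loglik_counts <- function(T, C) {
  sel <- C > 0
  sum(C[sel] * log(T[sel]))
}

# Hand-rolled slowest-relaxation estimate from a gap series: assign frames
# to the nearest well center, count well-to-well transitions at one lag by
# table(), row-normalize, and convert the second eigenvalue to a time.
well_relaxation_estimate <- function(g, centers, lag_frames, frame_dt) {
  w <- apply(abs(outer(g, centers, "-")), 1, which.min)
  n <- length(w)
  Tc <- unclass(table(factor(w[1:(n - lag_frames)], levels = seq_along(centers)),
                      factor(w[(1 + lag_frames):n], levels = seq_along(centers))))
  Tm <- Tc / rowSums(Tc)
  l2 <- sort(Re(eigen(Tm, only.values = TRUE)$values), decreasing = TRUE)[2]
  -lag_frames * frame_dt / log(l2)
}
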