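#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' least-squares deviation of `R X + t` from `Y`, with correspondence by row
#' index. The reflection branch of the SVD solution is resolved by
#' sign-correcting the smallest singular value, so a proper rotation
#' (`det = +1`) is always returned.
#'
#' @param X,Y `N x 3` coordinate matrices (Angstrom), `N >= 3`, matched rows.
#' @return A list of class `"superposition"` with elements `rotation` (3x3),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y))) stop("X and Y must have identical dimensions")
  if (ncol(X) != 3L) stop("coordinates must be N x 3")
  n <- nrow(X)
  if (n < 3L) stop("superposition needs at least 3 points, got ", n)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("degenerate point set (collinear points): superposition is not unique")
  }
  sgn <- sign(det(sv$v %*% t(sv$u)))
  if (sgn == 0) sgn <- 1
  D <- diag(c(1, 1, sgn))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  # residual-based rmsd avoids cancellation for near-congruent pairs
  resid <- sweep(X %*% t(R), 2, t, `+`) - Y
  structure(list(rotation = R, translation = t,
                 rmsd = sqrt(sum(resid^2) / n)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Root-mean-square deviation between two frames
#'
#' With `superpose = TRUE` (default) the minimized RMSD after optimal rigid
#' superposition is returned; otherwise the plain coordinate RMSD
#' \eqn{\sqrt{\sum_i \|X_i - Y_i\|^2 / N}}.
#'
#' @param X,Y `N x 3` coordinate matrices, matched rows.
#' @param superpose logical; minimize over rigid motions first?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(X, Y, superpose = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y))) stop("X and Y must have identical dimensions")
  if (superpose) return(kabsch_superpose(X, Y)$rmsd)
  sqrt(sum((X - Y)^2) / nrow(X))
}

#' Minimum inter-group distance in a frame
#'
#' The minimum Euclidean distance over all pairs of beads with one bead in
#' `groupA` and the other in `groupB` — the distance entering the SEL-LEL
#' contact observable.
#'
#' @param frame `n_beads x 3` coordinate matrix.
#' @param groups character vector of group tags, one per bead.
#' @param groupA,groupB group tags to compare.
#' @return Minimum distance in Angstrom.
#' @export
min_group_distance <- function(frame, groups, groupA, groupB) {
  frame <- as.matrix(frame)
  A <- frame[groups == groupA, , drop = FALSE]
  B <- frame[groups == groupB, , drop = FALSE]
  if (nrow(A) == 0L) stop("no beads carry group tag '", groupA, "'")
  if (nrow(B) == 0L) stop("no beads carry group tag '", groupB, "'")
  # explicit coordinate differences: exact pair distances, no expansion error
  ia <- rep(seq_len(nrow(A)), times = nrow(B))
  ib <- rep(seq_len(nrow(B)), each = nrow(A))
  sqrt(min(rowSums((A[ia, , drop = FALSE] - B[ib, , drop = FALSE])^2)))
}

#' Contact switching-function parameters
#'
#' Parameters of the rational switching function
#' \deqn{\mathrm{contact}(d) = \frac{1 - (d/d_0)^n}{1 - (d/d_0)^m}}
#' mapping an inter-loop distance to a contact value in (0, 1]. Defaults are
#' `d0 = 8` Angstrom, `n = 6`, `m = 12`.
#'
#' @param d0 cutoff distance in Angstrom (> 0).
#' @param n,m integer exponents with `0 < n < m`.
#' @return A list of class `"contact_params"`.
#' @export
contact_params <- function(d0 = 8.0, n = 6L, m = 12L) {
  if (!is.numeric(d0) || d0 <= 0) stop("d0 must be > 0")
  n <- as.integer(n); m <- as.integer(m)
  if (n <= 0 || m <= n) stop("exponents must satisfy 0 < n < m")
  structure(list(d0 = d0, n = n, m = m), class = "contact_params")
}

#' Rational switching-function contact value
#'
#' Evaluates `(1 - (d/d0)^n) / (1 - (d/d0)^m)`. The singularity at `d = d0`
#' is removable; the analytic limit `n/m` is returned there (0.5 for the
#' default `n = 6`, `m = 12`). Near `d0` the algebraically equivalent
#' geometric-series form \eqn{\sum_{k<n} r^k / \sum_{k<m} r^k} is used to
#' avoid catastrophic cancellation; for `m = 2n` the function equals
#' `1 / (1 + (d/d0)^n)` everywhere.
#'
#' @param d distance(s) in Angstrom, `>= 0`; vectorized.
#' @param params a [contact_params()].
#' @return Contact value(s) in (0, 1].
#' @export
contact <- function(d, params = contact_params()) {
  stopifnot(inherits(params, "contact_params"))
  if (any(d < 0)) stop("distance d must be non-negative")
  r <- d / params$d0
  out <- numeric(length(r))
  near <- abs(r - 1) < 1e-6
  if (any(near)) {
    # (1 - r^n)/(1 - r^m) = (sum_{k=0}^{n-1} r^k)/(sum_{k=0}^{m-1} r^k)
    rn <- r[near]
    num <- rowSums(outer(rn, 0:(params$n - 1L), `^`))
    den <- rowSums(outer(rn, 0:(params$m - 1L), `^`))
    out[near] <- num / den
  }
  if (any(!near)) {
    rf <- r[!near]
    out[!near] <- (1 - rf^params$n) / (1 - rf^params$m)
  }
  out
}
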