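#' All-vs-all minimized RMSD matrix
#'
#' Pairwise Kabsch-minimized RMSD between all frames of a trajectory pool
#' (compiled path; agrees with [rmsd()] to machine precision).
#'
#' @param pool a [trajectory()] or list of trajectories with a common bead
#'   count.
#' @return Symmetric `n x n` matrix of RMSD values (Angstrom).
#' @export
rmsd_matrix <- function(pool) {
  pc <- pool_cube(pool)
  rmsd_matrix_cpp(pc$cube)
}

#' Select reference structures by k-medoid clustering
#'
#' PAM-style k-medoids on the frame-vs-frame minimized-RMSD matrix:
#' k-means++-style seeding (seeded, distance-squared weighted), then
#' alternating assignment and exhaustive in-cluster medoid search until the
#' medoid set is stable. Medoids are actual frames, so RMSD-metric clustering
#' needs no coordinate averaging. For large pools a deterministic stride
#' subsample of at most `max_pool` frames is clustered.
#'
#' @param pool a [trajectory()] or list of trajectories.
#' @param k number of references (default 50).
#' @param seed integer seed.
#' @param max_pool cap on frames entering the RMSD matrix (default 2000).
#' @param max_iter PAM iteration cap.
#' @return A list of class `"reference_set"`: `structures` (list of
#'   `n_beads x 3` matrices), `source` (data.frame with traj/frame indices),
#'   `assignment` and `k`.
#' @export
select_references <- function(pool, k = 50L, seed = NULL, max_pool = 2000L,
                              max_iter = 100L) {
  pc <- pool_cube(pool)
  n_all <- dim(pc$cube)[3]
  if (k > n_all) stop("k = ", k, " exceeds the pool frame count ", n_all)
  sub <- if (n_all > max_pool) {
    unique(round(seq(1, n_all, length.out = max_pool)))
  } else seq_len(n_all)
  D <- rmsd_matrix_cpp(pc$cube[, , sub, drop = FALSE])
  n <- length(sub)
  if (k > n) stop("k exceeds the subsampled pool size ", n)
  med <- with_seed(seed, function() pam_medoids(D, k, max_iter))
  idx <- sub[med$medoids]
  structures <- lapply(idx, function(i) {
    matrix(pc$cube[, , i], ncol = 3L)
  })
  structure(list(structures = structures,
                 source = pc$prov[idx, , drop = FALSE],
                 assignment = med$assignment, k = k),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>", x$k, "medoid structures,",
      nrow(x$structures[[1]]), "beads each\n")
  invisible(x)
}

# PAM on a precomputed distance matrix. Seeding: first medoid uniform, the
# rest D(x)^2-weighted (k-means++ style). Uses the current RNG stream.
pam_medoids <- function(D, k, max_iter = 100L) {
  n <- nrow(D)
  med <- integer(k)
  med[1] <- sample.int(n, 1L)
  if (k > 1L) {
    for (j in 2:k) {
      dmin <- do.call(pmin, lapply(med[1:(j - 1L)], function(m) D[, m]))
      w <- dmin^2
      med[j] <- if (sum(w) > 0) sample.int(n, 1L, prob = w)
                else sample(setdiff(seq_len(n), med[1:(j - 1L)]), 1L)
    }
  }
  for (it in seq_len(max_iter)) {
    assignment <- apply(D[, med, drop = FALSE], 1, which.min)
    new_med <- vapply(seq_len(k), function(j) {
      members <- which(assignment == j)
      if (!length(members)) return(med[j])
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, integer(1))
    if (identical(new_med, med)) break
    med <- new_med
  }
  assignment <- apply(D[, med, drop = FALSE], 1, which.min)
  list(medoids = med, assignment = assignment)
}

#' RMSD-kernel features
#'
#' Featurizes every frame by its Gaussian-kernel-transformed minimized RMSD
#' to each reference structure:
#' \deqn{F_{ij} = \exp\left(-\mathrm{RMSD}(x_i, r_j)^2 / 2\sigma^2\right)}
#' with kernel width `sigma` (default 0.5 Angstrom). Values lie in (0, 1]
#' and are invariant to rigid motions of the frames.
#'
#' @param pool a [trajectory()] or list of trajectories.
#' @param refs a [select_references()] result, or a list of `n_beads x 3`
#'   reference coordinate matrices.
#' @param sigma kernel width in Angstrom (> 0).
#' @return Numeric matrix, frames x references, with attributes
#'   `"featurizer"` (`"rmsd_kernel"`), `"params"` and `"provenance"`.
#' @export
rmsd_kernel_features <- function(pool, refs, sigma = 0.5) {
  if (sigma <= 0) stop("sigma must be > 0")
  pc <- pool_cube(pool)
  structures <- if (inherits(refs, "reference_set")) refs$structures else refs
  nb <- dim(pc$cube)[1]
  if (any(vapply(structures, nrow, 1L) != nb)) {
    stop("reference bead count does not match the trajectory bead count ", nb)
  }
  rc <- array(0, dim = c(nb, 3L, length(structures)))
  for (j in seq_along(structures)) rc[, , j] <- structures[[j]]
  R <- rmsd_to_refs_cpp(pc$cube, rc)
  F <- exp(-R^2 / (2 * sigma^2))
  attr(F, "featurizer") <- "rmsd_kernel"
  attr(F, "params") <- list(sigma = sigma, n_refs = length(structures))
  attr(F, "provenance") <- pc$prov
  F
}

#' Superposed-coordinate features
#'
#' Superposes every frame onto a reference frame (Kabsch) and flattens the
#' transformed coordinates bead-major in x, y, z order — the raw positional
#' featurization used before PCA in the adaptive-sampling step.
#'
#' @param pool a [trajectory()] or list of trajectories.
#' @param ref `n_beads x 3` reference coordinates (default: first frame of
#'   the pool).
#' @return Numeric matrix, frames x (3 * n_beads), with provenance
#'   attributes as in [rmsd_kernel_features()].
#' @export
position_features <- function(pool, ref = NULL) {
  pc <- pool_cube(pool)
  nb <- dim(pc$cube)[1]
  if (is.null(ref)) ref <- matrix(pc$cube[, , 1], ncol = 3L)
  ref <- as.matrix(ref)
  if (nrow(ref) != nb) stop("reference bead count mismatch")
  nf <- dim(pc$cube)[3]
  F <- matrix(0, nf, 3L * nb)
  for (i in seq_len(nf)) {
    X <- matrix(pc$cube[, , i], ncol = 3L)
    sp <- kabsch_superpose(X, ref)
    Xs <- sweep(X %*% t(sp$rotation), 2, sp$translation, `+`)
    F[i, ] <- as.vector(t(Xs))   # bead-major x,y,z
  }
  attr(F, "featurizer") <- "positions"
  attr(F, "params") <- list(n_beads = nb)
  attr(F, "provenance") <- pc$prov
  F
}

#' PCA reduction of a feature matrix
#'
#' Mean-centered projection onto the leading variance eigenvectors. The sign
#' of each component is fixed by making its largest-magnitude loading
#' positive, so results are reproducible across linear-algebra backends.
#' Requesting more components than the matrix rank is an error.
#'
#' @param F frames x features numeric matrix.
#' @param n_components number of components to keep.
#' @return A list of class `"pca_reduction"`: `scores` (frames x
#'   n_components), `loadings`, `center`, `sdev` (component standard
#'   deviations, descending) and `var_explained`.
#' @export
pca_reduce <- function(F, n_components) {
  F <- as.matrix(F)
  if (n_components < 1 || n_components > ncol(F)) {
    stop("n_components must be in 1..", ncol(F))
  }
  pr <- prcomp(F, center = TRUE, scale. = FALSE)
  tol <- max(dim(F)) * .Machine$double.eps * pr$sdev[1]
  rank <- sum(pr$sdev > tol)
  if (n_components > rank) {
    stop("n_components = ", n_components, " exceeds the matrix rank ", rank)
  }
  L <- pr$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  L <- sweep(L, 2, flip, `*`)
  scores <- sweep(F, 2, pr$center) %*% L
  structure(list(scores = scores, loadings = L, center = pr$center,
                 sdev = pr$sdev[seq_len(n_components)],
                 var_explained = pr$sdev[seq_len(n_components)]^2 /
                   sum(pr$sdev^2)),
            class = "pca_reduction")
}

#' Project new data onto a fitted PCA reduction
#' @param object a [pca_reduce()] result.
#' @param newdata frames x features matrix on the original feature space.
#' @param ... unused.
#' @return Score matrix.
#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center) %*% object$loadings
}
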