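#' Discretizer factories for GMRQ cross-validation
#'
#' A discretizer is a function that is fitted on a list of training
#' trajectories and returns an assignment function mapping any trajectory to
#' integer microstate labels. Three factories are provided:
#'
#' * `discretizer_kernel_kmeans()` — the package's production pipeline:
#'   k-medoid reference selection on the training pool, RMSD-kernel
#'   featurization with width `sigma`, then k-means into `k` microstates.
#'   Assignment featurizes against the trained references and maps to the
#'   nearest trained center.
#' * `discretizer_identity()` — for trajectories that are already discrete
#'   (integer label vectors); the assignment is the identity.
#' * `discretizer_scrambled()` — control/baseline: assigns uniform random
#'   labels in `1..n_states`, destroying all kinetic information.
#'
#' @param n_refs,sigma,k,seed kernel-pipeline parameters (see
#'   [select_references()], [rmsd_kernel_features()],
#'   [kmeans_discretize()]).
#' @param n_states label count for the scrambled discretizer.
#' @return A function `fit(train_trajs)` returning `function(traj) labels`.
#' @name discretizers
NULL

#' @rdname discretizers
#' @export
discretizer_kernel_kmeans <- function(n_refs = 50L, sigma = 0.5, k = 500L,
                                      seed = 1L) {
  function(train_trajs) {
    refs <- select_references(train_trajs, k = n_refs, seed = seed)
    Ftr <- rmsd_kernel_features(train_trajs, refs, sigma = sigma)
    disc <- kmeans_discretize(Ftr, k = min(k, nrow(Ftr)), seed = seed)
    function(traj) {
      F <- rmsd_kernel_features(traj, refs, sigma = sigma)
      assign_frames(F, disc$centers)
    }
  }
}

#' @rdname discretizers
#' @export
discretizer_identity <- function() {
  function(train_trajs) function(traj) as.integer(traj)
}

#' @rdname discretizers
#' @export
discretizer_scrambled <- function(n_states) {
  function(train_trajs) {
    function(traj) {
      n <- if (inherits(traj, "trajectory")) n_frames(traj) else length(traj)
      sample.int(n_states, n, replace = TRUE)
    }
  }
}

#' GMRQ cross-validated score of a discretization pipeline
#'
#' Generalized matrix Rayleigh quotient scoring with trajectory-level
#' k-fold cross-validation: for each fold the discretizer is fitted on the
#' training trajectories and a Markov model is estimated from the training
#' labels; held-out trajectories are mapped onto the train-defined states,
#' and the test score is the sum of the `m_eigs` leading eigenvalues of the
#' transition matrix re-estimated from the held-out counts restricted to
#' the train-defined active set (further restricted to its largest
#' connected subset). By the variational principle of conformation
#' dynamics, finer kinetics-resolving discretizations score higher on
#' held-out data, up to the sum of the true leading eigenvalues.
#'
#' Folds are split at whole-trajectory granularity with a seeded shuffle,
#' so frames of one trajectory never straddle folds.
#'
#' @param trajs list of trajectories (or of integer label vectors when the
#'   discretizer is [discretizer_identity()] / scrambled).
#' @param discretizer a factory from [discretizers].
#' @param lag lag in steps.
#' @param n_folds number of folds (default 3, >= 2).
#' @param m_eigs number of leading eigenvalues summed (default 5, capped at
#'   the state count).
#' @param dt ns per step.
#' @param seed integer seed for the fold shuffle (and any stochastic
#'   discretizer).
#' @param reversible estimator for the fold models.
#' @return A list of class `"gmrq_result"`: `folds` (data.frame with
#'   per-fold train/test scores and validity flag), `mean_test_score`,
#'   `mean_train_score`, `n_folds`, `m_eigs`, `lag`, `dt`.
#' @export
gmrq_cv <- function(trajs, discretizer, lag, n_folds = 3L, m_eigs = 5L,
                    dt = 0.1, seed = NULL, reversible = TRUE) {
  stopifnot(is.list(trajs))
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (length(trajs) < n_folds) {
    stop("need at least n_folds = ", n_folds, " trajectories, got ",
         length(trajs))
  }
  res <- with_seed(seed, function() {
    fold_of <- sample(rep_len(seq_len(n_folds), length(trajs)))
    folds <- lapply(seq_len(n_folds), function(f) {
      train <- trajs[fold_of != f]
      test <- trajs[fold_of == f]
      assigner <- discretizer(train)
      dtr_train <- lapply(train, assigner)
      dtr_test <- lapply(test, assigner)
      m_train <- markov_model(dtr_train, lag = lag, dt = dt,
                              reversible = reversible)
      train_score <- sum_leading_eigs(m_train$transition_matrix, m_eigs)
      test_score <- tryCatch({
        Ct <- count_matrix(dtr_test, lag = lag,
                           n_states = max(unlist(dtr_train), unlist(dtr_test)))
        keep <- m_train$active_set
        Ct$counts <- Ct$counts[keep, keep, drop = FALSE]
        Ct$active_set <- keep
        if (sum(Ct$counts) == 0) stop("held-out fold visits no active state")
        Ct <- trim_to_connected(Ct)
        Tt <- transition_matrix(Ct, reversible = reversible)$T
        sum_leading_eigs(Tt, m_eigs)
      }, error = function(e) NA_real_)
      data.frame(fold = f, n_train = length(train), n_test = length(test),
                 train_score = train_score, test_score = test_score,
                 valid = is.finite(test_score))
    })
    do.call(rbind, folds)
  })
  structure(list(folds = res,
                 mean_test_score = mean(res$test_score[res$valid]),
                 mean_train_score = mean(res$train_score),
                 n_folds = n_folds, m_eigs = m_eigs,
                 lag = lag, dt = dt),
            class = "gmrq_result")
}

sum_leading_eigs <- function(T, m_eigs) {
  ev <- eigen(T, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  sum(Re(ev[seq_len(min(m_eigs, length(ev)))]))
}

#' @export
print.gmrq_result <- function(x, ...) {
  cat("<gmrq_result>", x$n_folds, "folds, m_eigs =", x$m_eigs,
      ", lag =", x$lag * x$dt, "ns\n")
  cat("  mean test score: ", format(x$mean_test_score, digits = 6),
      " (train ", format(x$mean_train_score, digits = 6), ")\n", sep = "")
  inv <- sum(!x$folds$valid)
  if (inv) cat("  ", inv, "fold(s) flagged invalid\n")
  invisible(x)
}
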