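#' Transition count matrix from discrete trajectories
#'
#' Counts observed transitions `(s_t, s_{t+lag})` in each discrete
#' trajectory. Sliding mode counts every start offset; strided mode counts
#' only offsets `1, 1+lag, 1+2*lag, ...`. Counts never cross trajectory
#' boundaries.
#'
#' @param dtrajs a list of integer state-label vectors (1-based), or a
#'   single vector.
#' @param lag lag in steps (>= 1).
#' @param n_states number of states (default: maximum observed label).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @return A list of class `"count_matrix"`: `counts` (k x k), `lag`,
#'   `mode`, `active_set` (original state ids of the rows, here `1..k`).
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL,
                         mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  dtrajs <- lapply(dtrajs, as.integer)
  if (lag < 1) stop("lag must be >= 1")
  if (any(vapply(dtrajs, function(d) any(d < 1L), TRUE))) {
    stop("state labels must be >= 1")
  }
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, 1L))
  usable <- vapply(dtrajs, length, 1L) > lag
  if (!any(usable)) {
    stop("no trajectory is longer than the lag (", lag, " steps)")
  }
  C <- matrix(0, n_states, n_states)
  for (d in dtrajs[usable]) {
    n <- length(d)
    starts <- if (mode == "sliding") seq_len(n - lag)
              else seq(1L, n - lag, by = lag)
    pairs <- table(factor(d[starts], levels = seq_len(n_states)),
                   factor(d[starts + lag], levels = seq_len(n_states)))
    C <- C + unclass(pairs)
  }
  dimnames(C) <- NULL
  structure(list(counts = C, lag = as.integer(lag), mode = mode,
                 active_set = seq_len(n_states)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "states, lag =", x$lag,
      "steps,", x$mode, "counting,", sum(x$counts), "transitions\n")
  invisible(x)
}

#' Restrict a count matrix to its largest connected set
#'
#' Keeps the strongly connected component of the directed count graph
#' carrying the most transition counts (ties broken toward more states,
#' then lowest state id). An ergodic (irreducible) count matrix is a
#' prerequisite for a valid stationary distribution.
#'
#' @param C a [count_matrix()].
#' @return A `"count_matrix"` whose `active_set` records the surviving
#'   original state ids.
#' @export
trim_to_connected <- function(C) {
  stopifnot(inherits(C, "count_matrix"))
  A <- C$counts > 0
  if (!any(A)) stop("count matrix has no transitions")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  scores <- vapply(seq_len(comp$no), function(ci) {
    m <- comp$membership == ci
    sum(C$counts[m, m, drop = FALSE])
  }, numeric(1))
  sizes <- as.numeric(comp$csize)
  best <- order(-scores, -sizes, seq_len(comp$no))[1]
  keep <- which(comp$membership == best)
  if (!length(keep)) stop("empty connected component")
  structure(list(counts = C$counts[keep, keep, drop = FALSE],
                 lag = C$lag, mode = C$mode,
                 active_set = C$active_set[keep]),
            class = "count_matrix")
}

# Reversible maximum-likelihood transition matrix via the standard
# fixed-point iteration on the symmetric flow matrix X (x_ij = x_ji):
#   x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)
# converged when the transition-matrix update falls below tol.
reversible_mle <- function(C, tol = 1e-10, max_iter = 10000L) {
  Cs <- C + t(C)
  ci <- rowSums(C)
  X <- Cs
  X <- X / sum(X)
  T_old <- X / rowSums(X)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    X_new <- ifelse(Cs > 0, Cs / denom, 0)
    X_new <- X_new / sum(X_new)
    T_new <- X_new / rowSums(X_new)
    delta <- max(abs(T_new - T_old))
    X <- X_new
    T_old <- T_new
    if (delta < tol) break
  }
  list(T = T_old, pi = rowSums(X) / sum(X), iterations = it)
}

#' Transition matrix from a count matrix
#'
#' Non-reversible: simple row normalization `T_ij = C_ij / sum_j C_ij`.
#' Reversible (default): maximum-likelihood estimate under the detailed
#' balance constraint by the standard fixed-point iteration on the
#' symmetric flow matrix, converged when the update falls below 1e-10.
#'
#' @param C a connected [count_matrix()] (see [trim_to_connected()]).
#' @param reversible estimate under detailed balance?
#' @return A list with `T` (row-stochastic), `pi` (stationary
#'   distribution) and `active_set`.
#' @export
transition_matrix <- function(C, reversible = TRUE) {
  stopifnot(inherits(C, "count_matrix"))
  if (any(rowSums(C$counts) == 0)) {
    stop("count matrix has a zero row; trim_to_connected() first")
  }
  if (reversible) {
    est <- reversible_mle(C$counts)
    list(T = est$T, pi = est$pi, active_set = C$active_set)
  } else {
    T <- C$counts / rowSums(C$counts)
    list(T = T, pi = stationary_distribution(T), active_set = C$active_set)
  }
}

#' Stationary distribution of a transition matrix
#'
#' The left eigenvector of eigenvalue 1, normalized to sum 1. Requires an
#' irreducible row-stochastic matrix (all stationary weights positive).
#'
#' @param T row-stochastic matrix.
#' @return Probability vector.
#' @export
stationary_distribution <- function(T) {
  T <- as.matrix(T)
  if (nrow(T) == 1L) return(1)
  rs <- rowSums(T)
  if (any(abs(rs - 1) > 1e-8)) stop("T is not row-stochastic")
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-6) stop("no unit eigenvalue found")
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-10 * max(abs(v)))) {
    stop("T appears reducible: stationary eigenvector has mixed signs")
  }
  v <- pmax(v, 0)
  v / sum(v)
}

#' Fit a Markov state model
#'
#' Estimates a discrete-state, discrete-lag Markov model of conformational
#' kinetics from discrete (microstate) trajectories: transitions are counted
#' at the chosen lag, the count graph is trimmed to its largest connected
#' set, and the transition matrix is estimated — by default the reversible
#' maximum-likelihood estimator, so the model satisfies detailed balance.
#'
#' @param dtrajs list of integer state-label vectors (1-based), or one
#'   vector.
#' @param lag lag time in steps (e.g. 200 steps of 0.1 ns for a 20 ns lag).
#' @param dt time per trajectory step in ns (default 0.1); `lag * dt` is the
#'   model lag time in ns.
#' @param reversible estimate under detailed balance (default TRUE).
#' @param mode transition counting mode, `"sliding"` or `"strided"`.
#' @param n_states number of states (default: maximum observed label).
#' @return An object of class `"markov_model"` with components
#'   `transition_matrix`, `stationary_distribution`, `eigenvalues` (sorted
#'   by modulus, descending), `counts`, `active_set` (original microstate
#'   ids of the model states), `lag` (steps), `dt` (ns), `lag_ns`,
#'   `reversible`.
#' @seealso [implied_timescales()], [ck_test()], [count_metastable()],
#'   [simulate.markov_model()], [reconstruct_trajectory()]
#' @export
markov_model <- function(dtrajs, lag, dt = 0.1, reversible = TRUE,
                         mode = "sliding", n_states = NULL) {
  C <- count_matrix(dtrajs, lag, n_states = n_states, mode = mode)
  C <- trim_to_connected(C)
  est <- transition_matrix(C, reversible = reversible)
  if (reversible) {
    # detailed balance makes T similar to a symmetric matrix, so the
    # spectrum is exactly real: solve the symmetrized problem
    sp <- sqrt(est$pi)
    S <- sp * est$T * rep(1 / sp, each = length(sp))
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    ev <- complex(real = ev[order(-abs(ev))], imaginary = 0)
  } else {
    ev <- eigen(est$T, only.values = TRUE)$values
    ev <- ev[order(-Mod(ev))]
  }
  structure(list(transition_matrix = est$T,
                 stationary_distribution = est$pi,
                 eigenvalues = ev,
                 counts = C,
                 active_set = C$active_set,
                 lag = as.integer(lag), dt = dt, lag_ns = lag * dt,
                 reversible = reversible),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  k <- nrow(x$transition_matrix)
  cat("<markov_model>", k, "states, lag =", x$lag_ns, "ns",
      if (x$reversible) "(reversible MLE)" else "(row-normalized)", "\n")
  ts <- timescales(x, k_eigs = min(4L, k))
  cat("  slowest implied timescales (ns):",
      paste(ifelse(is.na(ts), "n/a", format(ts, digits = 4)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.markov_model <- function(object, ...) {
  k <- nrow(object$transition_matrix)
  out <- list(n_states = k,
              lag_ns = object$lag_ns,
              reversible = object$reversible,
              total_counts = sum(object$counts$counts),
              stationary = object$stationary_distribution,
              timescales_ns = timescales(object, k_eigs = min(6L, k)),
              n_metastable = count_metastable(object))
  class(out) <- "summary.markov_model"
  out
}

#' @export
print.summary.markov_model <- function(x, ...) {
  cat("Markov state model summary\n")
  cat("  states:            ", x$n_states, "\n")
  cat("  lag time:          ", x$lag_ns, "ns\n")
  cat("  estimator:         ",
      if (x$reversible) "reversible MLE" else "row-normalized", "\n")
  cat("  transition counts: ", x$total_counts, "\n")
  cat("  metastable states: ", x$n_metastable, "\n")
  ts <- x$timescales_ns
  cat("  implied timescales (ns):",
      paste(ifelse(is.na(ts), "n/a", format(ts, digits = 4)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.markov_model <- function(object, ...) object$transition_matrix

#' Propagate a state distribution with a fitted model
#'
#' Returns the state distribution after `n_lags` lag times, starting from a
#' single state or a distribution over the model states.
#'
#' @param object a [markov_model()].
#' @param from starting state index (within the model's active set) or a
#'   probability vector; default: the stationary distribution.
#' @param n_lags number of lag steps to propagate.
#' @param ... unused.
#' @return Probability vector over the model states.
#' @export
predict.markov_model <- function(object, from = NULL, n_lags = 1L, ...) {
  k <- nrow(object$transition_matrix)
  p <- if (is.null(from)) object$stationary_distribution
       else if (length(from) == 1L) {
         v <- numeric(k); v[from] <- 1; v
       } else from
  if (length(p) != k) stop("`from` must have length ", k)
  for (i in seq_len(n_lags)) p <- as.vector(p %*% object$transition_matrix)
  p
}

#' Simulate a state chain from a fitted model
#'
#' @param object a [markov_model()].
#' @param nsim chain length in lag steps.
#' @param seed integer seed.
#' @param start starting state (model-internal index) or probability
#'   vector; default: drawn from the stationary distribution.
#' @param ... unused.
#' @return Integer vector of model-internal state indices (1-based); the
#'   original microstate ids are `object$active_set[states]`.
#' @export
simulate.markov_model <- function(object, nsim = 1L, seed = NULL,
                                  start = NULL, ...) {
  if (is.null(start)) start <- object$stationary_distribution
  sample_discrete_chain(object$transition_matrix, nsim, seed = seed,
                        initial = start, lag_unit = object$lag_ns)
}

#' Implied timescales of a fitted model
#'
#' \eqn{t_i = -\tau / \log \lambda_i(\tau)} for the eigenvalues below the
#' stationary one. Complex or non-positive eigenvalues have no real
#' timescale and yield `NA` (flagged, never silently dropped).
#'
#' @param model a [markov_model()].
#' @param k_eigs number of timescales.
#' @return Numeric vector in ns (NA where undefined).
#' @export
timescales <- function(model, k_eigs = 5L) {
  ev <- model$eigenvalues
  n <- min(k_eigs, length(ev) - 1L)
  if (n < 1L) return(numeric(0))
  vapply(seq_len(n) + 1L, function(i) {
    l <- ev[i]
    if (abs(Im(l)) > 1e-10 || Re(l) <= 0 || Re(l) >= 1) return(NA_real_)
    -model$lag_ns / log(Re(l))
  }, numeric(1))
}

#' Implied-timescale table over a set of lags
#'
#' Fits one model per lag and tabulates the implied timescales
#' `-tau / log(lambda_i)`. Lag-independence of the timescales diagnoses
#' Markovianity at the chosen discretization.
#'
#' @param dtrajs list of discrete trajectories.
#' @param lags integer vector of lags (steps).
#' @param dt time per step in ns.
#' @param k_eigs timescales per lag.
#' @param reversible passed to [markov_model()].
#' @return A data.frame of class `"its_table"` with columns `lag_steps`,
#'   `lag_ns`, `index`, `timescale_ns` (NA where the eigenvalue is complex
#'   or non-positive).
#' @export
implied_timescales <- function(dtrajs, lags, dt = 0.1, k_eigs = 3L,
                               reversible = TRUE) {
  rows <- lapply(lags, function(l) {
    m <- markov_model(dtrajs, lag = l, dt = dt, reversible = reversible)
    ts <- timescales(m, k_eigs)
    if (!length(ts)) return(NULL)
    data.frame(lag_steps = l, lag_ns = l * dt, index = seq_along(ts) + 1L,
               timescale_ns = ts)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("its_table", "data.frame")
  out
}

#' @export
plot.its_table <- function(x, ...) {
  idx <- sort(unique(x$index))
  cols <- grDevices::hcl.colors(max(3L, length(idx)), "Dark 3")
  ylim <- range(c(x$timescale_ns, x$lag_ns), na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$lag_ns), ylim = ylim, log = "y",
                 xlab = "lag time (ns)", ylab = "implied timescale (ns)", ...)
  for (j in seq_along(idx)) {
    sub <- x[x$index == idx[j], ]
    graphics::lines(sub$lag_ns, sub$timescale_ns, col = cols[j], type = "b",
                    pch = 16)
  }
  graphics::lines(range(x$lag_ns), range(x$lag_ns), lty = 2, col = "grey40")
  graphics::legend("topleft", legend = paste0("t", idx), col = cols[seq_along(idx)],
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Chapman-Kolmogorov test
#'
#' Compares the propagated model `T(tau)^f` against a model re-estimated at
#' lag `f * tau`, on the states common to both, for each factor `f`. Small
#' deviations support the Markov assumption at lag `tau`.
#'
#' @param dtrajs list of discrete trajectories.
#' @param lag base lag in steps.
#' @param factors integer factors (>= 2).
#' @param dt ns per step.
#' @param reversible passed to [markov_model()].
#' @return data.frame with `factor`, `lag_ns`, `max_deviation` (max
#'   absolute element-wise difference; NA with a warning when the data
#'   cannot support the longer lag).
#' @export
ck_test <- function(dtrajs, lag, factors = c(2L, 4L), dt = 0.1,
                    reversible = TRUE) {
  if (any(factors < 2)) stop("factors must be >= 2")
  base <- markov_model(dtrajs, lag, dt = dt, reversible = reversible)
  out <- lapply(factors, function(f) {
    dev <- tryCatch({
      long <- markov_model(dtrajs, lag * f, dt = dt, reversible = reversible)
      common <- intersect(base$active_set, long$active_set)
      if (!length(common)) stop("no common states")
      Pf <- matpow(base$transition_matrix, f)
      i1 <- match(common, base$active_set)
      i2 <- match(common, long$active_set)
      max(abs(Pf[i1, i1, drop = FALSE] -
                long$transition_matrix[i2, i2, drop = FALSE]))
    }, error = function(e) {
      warning("ck_test: factor ", f, " not estimable (", conditionMessage(e),
              ")", call. = FALSE)
      NA_real_
    })
    data.frame(factor = f, lag_ns = lag * f * dt, max_deviation = dev)
  })
  do.call(rbind, out)
}

matpow <- function(M, p) {
  out <- diag(nrow(M))
  base <- M
  while (p > 0) {
    if (p %% 2 == 1) out <- out %*% base
    base <- base %*% base
    p <- p %/% 2
  }
  out
}

#' Count metastable states by the spectral gap
#'
#' Orders the transition-matrix eigenvalues by modulus, keeps the leading
#' real positive ones, and returns the number of eigenvalues before the
#' largest relative gap \eqn{(\lambda_i - \lambda_{i+1}) / \lambda_i} among
#' the top `k_max` candidates. A three-well system, for example, has three
#' eigenvalues near 1 followed by a sharp drop.
#'
#' @param model a [markov_model()] or a row-stochastic matrix.
#' @param k_max number of leading eigenvalues to consider (default 10).
#' @return Integer number of metastable states (1 for a single-state or
#'   gap-free spectrum).
#' @export
count_metastable <- function(model, k_max = 10L) {
  ev <- if (inherits(model, "markov_model")) model$eigenvalues
        else eigen(as.matrix(model), only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  lam <- Re(ev[abs(Im(ev)) < 1e-8 & Re(ev) > 0])
  lam <- lam[seq_len(min(length(lam), k_max))]
  if (length(lam) < 2L) return(1L)
  gaps <- (lam[-length(lam)] - lam[-1]) / lam[-length(lam)]
  which.max(gaps)
}

#' @export
plot.markov_model <- function(x, k_eigs = 10L, ...) {
  ev <- Mod(x$eigenvalues)[seq_len(min(k_eigs, length(x$eigenvalues)))]
  graphics::plot(seq_along(ev), ev, type = "h", lwd = 3,
                 xlab = "eigenvalue index", ylab = "|eigenvalue|",
                 ylim = c(0, 1.05), ...)
  graphics::points(seq_along(ev), ev, pch = 16)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Index pool frames by model state
#'
#' Maps every frame of the discrete trajectories to its model state,
#' returning for each state the global frame positions (rows of the pooled
#' frame table, i.e. trajectories concatenated in list order). Used as the
#' emission table for [reconstruct_trajectory()].
#'
#' @param dtrajs the discrete trajectories the model was fitted on.
#' @param model a [markov_model()].
#' @return List of integer vectors, one per model state.
#' @export
build_frame_index <- function(dtrajs, model) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  labels <- unlist(dtrajs, use.names = FALSE)
  lapply(model$active_set, function(s) which(labels == s))
}

#' Reconstruct a long pseudo-trajectory from a fitted model
#'
#' Samples a discrete chain of `n_steps` from the transition matrix and
#' emits, for each visited state, one uniformly chosen stored frame of that
#' state. Each step advances wall time by the model lag, so the
#' reconstructed span is `n_steps * lag_ns` (e.g. 5000 steps at a 20 ns lag
#' span 100 us).
#'
#' @param model a [markov_model()].
#' @param frame_index per-state frame positions from [build_frame_index()].
#' @param n_steps chain length.
#' @param seed integer seed.
#' @param start starting state or distribution (default: stationary).
#' @return A list of class `"reconstructed_trajectory"`: `states`
#'   (model-internal), `frames` (global pool frame positions), `times_ns`,
#'   `lag_ns`, `span_ns`.
#' @export
reconstruct_trajectory <- function(model, frame_index, n_steps, seed = NULL,
                                   start = NULL) {
  k <- nrow(model$transition_matrix)
  if (length(frame_index) != k) {
    stop("frame_index must have one entry per model state (", k, ")")
  }
  empty <- which(vapply(frame_index, length, 1L) == 0L)
  if (length(empty)) {
    stop("model state(s) without stored frames: ",
         paste(empty, collapse = ", "))
  }
  # flatten the emission table for vectorized uniform frame draws
  all_frames <- unlist(frame_index, use.names = FALSE)
  lens <- lengths(frame_index)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  out <- with_seed(seed, function() {
    states <- as.integer(simulate.markov_model(model, nsim = n_steps,
                                               start = start))
    pos <- ceiling(runif(n_steps) * lens[states])
    pos[pos < 1L] <- 1L
    list(states = states, frames = all_frames[starts[states] + pos])
  })
  structure(list(states = out$states, frames = out$frames,
                 times_ns = (seq_len(n_steps) - 1) * model$lag_ns,
                 lag_ns = model$lag_ns,
                 span_ns = n_steps * model$lag_ns),
            class = "reconstructed_trajectory")
}

#' @export
print.reconstructed_trajectory <- function(x, ...) {
  span <- x$span_ns
  unit <- if (span >= 1e6) c(1e6, "ms") else if (span >= 1e3) c(1e3, "us")
          else c(1, "ns")
  cat("<reconstructed_trajectory>", length(x$states), "steps at lag",
      x$lag_ns, "ns; span", format(span / as.numeric(unit[1]), digits = 4),
      unit[2], "\n")
  invisible(x)
}
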