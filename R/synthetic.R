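#' Multi-well gap potential
#'
#' A smooth free-energy profile along the loop-separation ("gap") coordinate,
#' built as a log-sum of Gaussian wells:
#' \deqn{U(g) = -kT \log \sum_i \exp\left(D_i - (g - c_i)^2 / 2 s_i^2\right)}
#' so that well `i` sits at `c_i` with depth about `D_i` (in kT units) and
#' width `s_i`. The Boltzmann density `exp(-U/kT)` is then a Gaussian mixture
#' with closed form, which the simulator's stationary tests exploit.
#'
#' @param centers well centers in Angstrom, strictly increasing.
#' @param depths well depths in kT units (larger = deeper = more populated).
#' @param widths well standard deviations in Angstrom, all > 0.
#' @param kT energy scale (default 1).
#' @param description free-text note.
#' @return A list of class `"potential_spec"`.
#' @export
potential_spec <- function(centers, depths, widths, kT = 1,
                           description = "") {
  stopifnot(length(centers) >= 1,
            length(depths) == length(centers),
            length(widths) == length(centers))
  if (any(widths <= 0)) stop("well widths must be > 0")
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("well centers must be strictly increasing")
  }
  if (kT <= 0) stop("kT must be > 0")
  structure(list(centers = as.numeric(centers), depths = as.numeric(depths),
                 widths = as.numeric(widths), kT = kT,
                 description = description),
            class = "potential_spec")
}

#' Evaluate a gap potential
#' @param potential a [potential_spec()].
#' @param g gap value(s) in Angstrom; vectorized.
#' @return `U(g)` in absolute energy units (kT-scaled).
#' @export
potential_energy <- function(potential, g) {
  stopifnot(inherits(potential, "potential_spec"))
  a <- outer(g, potential$centers, `-`)
  a <- sweep(a, 2, potential$widths, `/`)
  a <- sweep(-a^2 / 2, 2, potential$depths, `+`)
  amax <- apply(a, 1, max)
  -potential$kT * (log(rowSums(exp(a - amax))) + amax)
}

#' Stationary (Boltzmann) density of a gap potential
#'
#' The normalized equilibrium density `exp(-U/kT)/Z`, available in closed
#' form as a Gaussian mixture with weights proportional to
#' `exp(depth_i) * width_i`.
#'
#' @param potential a [potential_spec()].
#' @param g gap value(s).
#' @return Density value(s).
#' @export
boltzmann_density <- function(potential, g) {
  w <- exp(potential$depths) * potential$widths
  w <- w / sum(w)
  comp <- vapply(seq_along(w), function(i) {
    w[i] * stats::dnorm(g, potential$centers[i], potential$widths[i])
  }, numeric(length(g)))
  if (length(g) == 1L) sum(comp) else rowSums(comp)
}

#' Equilibrium well populations of a gap potential
#' @param potential a [potential_spec()].
#' @return Probability vector, one entry per well (mixture weights
#'   `exp(depth_i) * width_i`, normalized; exact up to well overlap).
#' @export
well_populations <- function(potential) {
  w <- exp(potential$depths) * potential$widths
  w / sum(w)
}

#' Sample a discrete Markov chain
#'
#' Draws a state sequence from a row-stochastic transition matrix. The first
#' label is the initial state; each subsequent label is drawn from the row of
#' its predecessor. Used as the ground-truth generator for estimator-recovery
#' tests and by trajectory reconstruction.
#'
#' @param T row-stochastic `k x k` matrix (rows sum to 1 within 1e-9).
#' @param n_steps number of labels to return (>= 1).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param initial either a single starting state (1-based) or a probability
#'   vector of length `k` to draw it from.
#' @return Integer vector of `n_steps` state labels in `1..k`, with
#'   attribute `"lag_unit"` (ns per step, taken from `lag_unit`).
#' @param lag_unit time per step in ns (metadata; default 1).
#' @export
sample_discrete_chain <- function(T, n_steps, seed = NULL, initial = 1L,
                                  lag_unit = 1) {
  T <- as.matrix(T)
  if (nrow(T) != ncol(T)) stop("T must be square")
  rs <- rowSums(T)
  bad <- which(abs(rs - 1) > 1e-9 | apply(T < 0, 1, any))
  if (length(bad)) {
    stop("T is not row-stochastic: row ", bad[1], " sums to ",
         format(rs[bad[1]], digits = 10), " or has negative entries")
  }
  if (n_steps < 1) stop("n_steps must be >= 1")
  cumT <- t(apply(T, 1, cumsum))
  cumT[, ncol(cumT)] <- 1  # guard against rounding
  if (ncol(T) == 1L) cumT <- matrix(cumT, 1L, 1L)
  labels <- with_seed(seed, function() {
    init <- if (length(initial) == 1L) as.integer(initial)
            else sample.int(nrow(T), 1L, prob = initial)
    if (init < 1L || init > nrow(T)) stop("initial state out of range")
    sample_chain_cpp(cumT, as.integer(n_steps), init)
  })
  attr(labels, "lag_unit") <- lag_unit
  labels
}

#' Overdamped Langevin simulation of the gap coordinate
#'
#' Integrates the Brownian-dynamics update
#' \deqn{g \leftarrow g - \Delta t\, U'(g)/\gamma +
#'       \sqrt{2 kT \Delta t / \gamma}\,\xi,\qquad \xi \sim N(0,1)}
#' on a [potential_spec()]. The returned series holds the gap at steps
#' `0, stride, 2*stride, ...`, so `stride` implements frame subsampling
#' (e.g. an internal `dt` of 5e-4 ns recorded every 200 steps gives the
#' 0.1 ns frame stride used throughout the package).
#'
#' @param potential a [potential_spec()].
#' @param n_steps number of integrator steps (>= 1; the initial value counts
#'   as step 0).
#' @param dt integrator time step in ns.
#' @param friction friction coefficient `gamma` (1/ns scale; diffusion
#'   constant is `kT/friction`).
#' @param seed integer seed for reproducibility.
#' @param x0 initial gap in Angstrom.
#' @param stride record every `stride`-th step (default 1).
#' @param bound divergence guard: error if `|g|` exceeds this (default 1e3).
#' @return Numeric vector of recorded gap values, attribute `"dt"` holding
#'   the time between recorded values (`dt * stride`, ns).
#' @export
simulate_langevin_gap <- function(potential, n_steps, dt = 5e-4,
                                  friction = 1, seed = NULL,
                                  x0 = potential$centers[1], stride = 1L,
                                  bound = 1e3) {
  stopifnot(inherits(potential, "potential_spec"))
  if (dt <= 0) stop("dt must be > 0")
  if (friction <= 0) stop("friction must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  g <- with_seed(seed, function() {
    langevin_gap_cpp(potential$centers, potential$depths, potential$widths,
                     potential$kT, x0, as.numeric(n_steps), dt, friction,
                     as.integer(stride), bound)
  })
  attr(g, "dt") <- dt * stride
  g
}

#' Coarse two-loop bead model
#'
#' Bead templates for the two extracellular loops: a fixed short loop (SEL)
#' and a large loop (LEL) that is rigidly translated along `gap_axis` by the
#' gap coordinate. Both default templates contain one bead on the axis origin
#' so that, without jitter, the minimum SEL-LEL distance equals the gap
#' exactly (baseline offset 0).
#'
#' @param sel_template,lel_template `n x 3` coordinate matrices (each with at
#'   least 3 non-collinear beads).
#' @param jitter_sd isotropic per-bead Gaussian jitter sd in Angstrom (>= 0).
#' @param gap_axis unit 3-vector along which the LEL is displaced.
#' @return A list of class `"loop_model_spec"`.
#' @export
loop_model_spec <- function(sel_template = default_sel_template(),
                            lel_template = default_lel_template(),
                            jitter_sd = 0.2,
                            gap_axis = c(0, 0, 1)) {
  sel_template <- as.matrix(sel_template)
  lel_template <- as.matrix(lel_template)
  for (tm in list(sel_template, lel_template)) {
    if (nrow(tm) < 3L || ncol(tm) != 3L) stop("templates must be >= 3 x 3")
    s <- svd(sweep(tm, 2, colMeans(tm)))$d
    if (s[2] < 1e-8) stop("template beads are collinear")
  }
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  gap_axis <- gap_axis / sqrt(sum(gap_axis^2))
  structure(list(sel_template = sel_template, lel_template = lel_template,
                 jitter_sd = jitter_sd, gap_axis = gap_axis),
            class = "loop_model_spec")
}

#' @rdname loop_model_spec
#' @export
default_sel_template <- function() {
  matrix(c(0.0,  0.0,  0.0,
           1.5,  0.0, -0.5,
          -1.5,  0.3, -0.6,
           0.5,  1.4, -1.0,
          -0.6, -1.3, -0.9,
           0.2,  0.5, -1.8), ncol = 3, byrow = TRUE)
}

#' @rdname loop_model_spec
#' @export
default_lel_template <- function() {
  matrix(c(0.0,  0.0,  0.0,
           1.2,  0.4,  0.6,
          -1.1,  0.5,  0.5,
           0.3, -1.2,  0.8,
          -0.4,  1.3,  0.9,
           1.8, -0.8,  1.2,
          -1.7, -0.6,  1.4,
           0.8,  1.8,  1.6,
          -0.9, -1.6,  1.9,
           0.1,  0.2,  2.4), ncol = 3, byrow = TRUE)
}

#' Embed a gap series as a 3-D bead trajectory
#'
#' Each frame holds the SEL template in place and the LEL template translated
#' by the frame's gap value along the gap axis, with iid isotropic Gaussian
#' jitter of sd `jitter_sd` added to every bead coordinate.
#'
#' @param gaps numeric vector of gap values (Angstrom); attribute `"dt"` (ns)
#'   is used as the frame time step if present.
#' @param spec a [loop_model_spec()].
#' @param seed integer seed for the jitter.
#' @param dt frame time step in ns (default: `attr(gaps, "dt")` or 0.1).
#' @param id optional trajectory id.
#' @return A [trajectory()] with group tags `"SEL"` and `"LEL"`.
#' @export
embed_loop_frames <- function(gaps, spec = loop_model_spec(), seed = NULL,
                              dt = NULL, id = NULL) {
  stopifnot(inherits(spec, "loop_model_spec"))
  if (!all(is.finite(gaps))) stop("gap values must be finite")
  if (is.null(dt)) dt <- if (!is.null(attr(gaps, "dt"))) attr(gaps, "dt") else 0.1
  nf <- length(gaps)
  ns <- nrow(spec$sel_template); nl <- nrow(spec$lel_template)
  nb <- ns + nl
  coords <- array(0, dim = c(nf, nb, 3L))
  for (i in seq_len(nf)) {
    lel <- sweep(spec$lel_template, 2, gaps[i] * spec$gap_axis, `+`)
    coords[i, , ] <- rbind(spec$sel_template, lel)
  }
  if (spec$jitter_sd > 0) {
    coords <- coords + with_seed(seed, function() {
      array(rnorm(nf * nb * 3L, sd = spec$jitter_sd), dim = c(nf, nb, 3L))
    })
  }
  trajectory(coords, c(rep("SEL", ns), rep("LEL", nl)), dt = dt, id = id)
}

#' Default three-well loop surrogate system
#'
#' The fixed, versioned synthetic system used throughout the package: a
#' three-well gap potential (closed / semi-open / open loop conformations at
#' 4, 8.5 and 14 Angstrom), the default two-loop bead model, simulation
#' parameters (internal dt 5e-4 ns, friction 1, 0.1 ns frame stride), and a
#' ground-truth block with the equilibrium well populations (closed form),
#' the reference relaxation timescales of the gap diffusion (computed by
#' [gap_relaxation_timescales()]), and the 3-state transition matrix at the
#' default 20 ns lag implied by those dynamics.
#'
#' @return A list of class `"loop_system"` with elements `potential`,
#'   `loop_spec`, `sim` (dt, friction, frame_stride, frame_dt) and
#'   `ground_truth` (populations, timescales ns, transition matrix, lag ns).
#' @export
default_loop_system <- function() {
  pot <- potential_spec(centers = c(4.0, 8.5, 14.0),
                        depths  = c(2.0, 1.5, 1.8),
                        widths  = c(0.8, 0.8, 0.9),
                        kT = 1,
                        description = "closed / semi-open / open loop gap")
  sim <- list(dt = 5e-4, friction = 1, frame_stride = 200L, frame_dt = 0.1)
  ts <- gap_relaxation_timescales(pot, friction = sim$friction, n_eigs = 2L)
  gt <- list(populations = well_populations(pot),
             timescales = ts,
             lag = 20,
             transition_matrix = gap_well_transition_matrix(pot, lag = 20,
                                                            friction = sim$friction))
  structure(list(potential = pot, loop_spec = loop_model_spec(),
                 sim = sim, ground_truth = gt),
            class = "loop_system")
}

#' @export
print.loop_system <- function(x, ...) {
  cat("<loop_system>", length(x$potential$centers), "wells at",
      paste(x$potential$centers, collapse = ", "), "A\n")
  cat("  populations:", paste(round(x$ground_truth$populations, 3),
                              collapse = " "), "\n")
  cat("  slowest timescales (ns):",
      paste(round(x$ground_truth$timescales, 1), collapse = " "), "\n")
  invisible(x)
}

#' Exact relaxation timescales of the 1-D gap diffusion
#'
#' Discretizes the overdamped (Smoluchowski) generator of diffusion on the
#' gap potential onto a fine grid — nearest-neighbour hopping rates
#' \eqn{k_{ij} = D/h^2 \exp(-(U_j - U_i)/2kT)} obey detailed balance with
#' respect to the Boltzmann weights — and returns the slowest relaxation
#' times `-1/lambda_i` from the symmetrized generator spectrum. Serves as the
#' deterministic reference for the simulator's kinetics.
#'
#' @param potential a [potential_spec()].
#' @param friction friction coefficient (diffusion constant `kT/friction`).
#' @param n_grid grid resolution (default 600).
#' @param pad Angstrom padding beyond the outermost well centers.
#' @param n_eigs number of timescales to return.
#' @return Numeric vector of timescales in ns, sorted descending.
#' @export
gap_relaxation_timescales <- function(potential, friction = 1, n_grid = 600L,
                                      pad = 5, n_eigs = 2L) {
  stopifnot(inherits(potential, "potential_spec"))
  sm <- smoluchowski_spectrum(potential, friction, n_grid, pad)
  lam <- sm$values[2:(n_eigs + 1L)]
  sort(-1 / lam, decreasing = TRUE)
}

# Discretized Smoluchowski generator of the 1-D gap diffusion on a uniform
# grid. Nearest-neighbour rates k_{i,i+1} = D/h^2 exp(-(U_{i+1}-U_i)/2kT)
# satisfy detailed balance w.r.t. the Boltzmann weights; the similarity
# transform S = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric tridiagonal
# with constant off-diagonal D/h^2, so eigen(S) gives the exact spectrum.
smoluchowski_spectrum <- function(potential, friction, n_grid, pad) {
  lo <- min(potential$centers) - pad
  hi <- max(potential$centers) + pad
  x <- seq(lo, hi, length.out = n_grid)
  h <- x[2] - x[1]
  U <- potential_energy(potential, x) / potential$kT
  D <- potential$kT / friction
  kup <- (D / h^2) * exp(-(U[-1] - U[-n_grid]) / 2)   # i -> i+1, i = 1..n-1
  kdn <- (D / h^2) * exp(-(U[-n_grid] - U[-1]) / 2)   # i+1 -> i
  diag_main <- numeric(n_grid)
  diag_main[1:(n_grid - 1)] <- diag_main[1:(n_grid - 1)] - kup
  diag_main[2:n_grid] <- diag_main[2:n_grid] - kdn
  S <- matrix(0, n_grid, n_grid)
  diag(S) <- diag_main
  S[cbind(1:(n_grid - 1), 2:n_grid)] <- D / h^2
  S[cbind(2:n_grid, 1:(n_grid - 1))] <- D / h^2
  es <- eigen(S, symmetric = TRUE)
  logpi <- -U - max(-U)
  piw <- exp(logpi); piw <- piw / sum(piw)
  list(x = x, pi = piw, values = es$values, vectors = es$vectors)
}

#' Well-to-well transition matrix implied by the gap diffusion
#'
#' Propagates the discretized Smoluchowski generator over one lag time and
#' coarse-grains the resulting propagator onto the wells (each grid point
#' assigned to the nearest well center), giving the reference row-stochastic
#' transition matrix that an exact MSM of the surrogate should recover.
#'
#' @inheritParams gap_relaxation_timescales
#' @param lag lag time in ns.
#' @return `n_wells x n_wells` row-stochastic matrix.
#' @export
gap_well_transition_matrix <- function(potential, lag, friction = 1,
                                       n_grid = 400L, pad = 5) {
  sm <- smoluchowski_spectrum(potential, friction, n_grid, pad)
  # P(lag) = diag(1/sqrt(pi)) V exp(lag * Lambda) V' diag(sqrt(pi))
  sp <- sqrt(sm$pi)
  E <- sm$vectors %*% (exp(lag * sm$values) * t(sm$vectors))
  P <- (1 / sp) * E * rep(sp, each = length(sp))
  well <- apply(abs(outer(sm$x, potential$centers, `-`)), 1, which.min)
  k <- length(potential$centers)
  T <- matrix(0, k, k)
  for (a in seq_len(k)) {
    wa <- sm$pi * (well == a)
    wa <- wa / sum(wa)
    rowP <- as.vector(wa %*% P)
    for (b in seq_len(k)) T[a, b] <- sum(rowP[well == b])
  }
  T / rowSums(T)
}

#' Simulate one surrogate loop trajectory
#'
#' Runs the overdamped gap dynamics of a [default_loop_system()] (or any
#' `loop_system`), subsamples at the system's frame stride (0.1 ns by
#' default), and embeds the gap series as a jittered bead trajectory.
#'
#' @param system a `loop_system`.
#' @param n_frames_out number of frames to produce.
#' @param seed integer seed (drives both the dynamics and the jitter).
#' @param x0 initial gap (default: drawn from the well populations).
#' @param id optional trajectory id.
#' @return A [trajectory()]; the underlying gap series is attached as
#'   attribute `"gaps"`.
#' @export
simulate_loop_trajectory <- function(system, n_frames_out, seed = NULL,
                                     x0 = NULL, id = NULL) {
  stopifnot(inherits(system, "loop_system"))
  with_seed(seed, function() {
    if (is.null(x0)) {
      w <- sample.int(length(system$potential$centers), 1L,
                      prob = system$ground_truth$populations)
      x0 <- system$potential$centers[w]
    }
    stride <- system$sim$frame_stride
    g <- simulate_langevin_gap(system$potential,
                               n_steps = n_frames_out * stride,
                               dt = system$sim$dt,
                               friction = system$sim$friction,
                               x0 = x0, stride = stride)
    g <- g[seq_len(n_frames_out)]
    traj <- embed_loop_frames(g, system$loop_spec,
                              dt = system$sim$frame_dt, id = id)
    attr(traj, "gaps") <- g
    traj
  })
}
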