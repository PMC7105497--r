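test_that("discrete chain sampling honors the transition matrix", {
  # absorbing identity
  lab <- sample_discrete_chain(diag(2), 100, seed = 1, initial = 1L)
  expect_true(all(lab == 1L))

  # determinism
  T <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  a <- sample_discrete_chain(T, 5000, seed = 42)
  b <- sample_discrete_chain(T, 5000, seed = 42)
  expect_identical(as.integer(a), as.integer(b))

  # empirical transition frequencies within 3 binomial standard errors
  lab <- as.integer(sample_discrete_chain(T, 1e6, seed = 1))
  n <- length(lab)
  from <- lab[-n]; to <- lab[-1]
  for (i in 1:2) {
    ni <- sum(from == i)
    phat <- sum(from == i & to == i) / ni
    expect_lt(abs(phat - 0.9), 3 * sqrt(0.9 * 0.1 / ni))
  }

  # validation names the offending row
  bad <- matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_error(sample_discrete_chain(bad, 10), "row 1")
})

test_that("langevin dynamics: fixed point, Boltzmann statistics, ergodicity", {
  # vanishing temperature: both drift and noise scale with kT, so a start
  # at the minimum stays there
  pot1 <- potential_spec(5, 2, 0.7, kT = 1e-12)
  g <- simulate_langevin_gap(pot1, 1e4, dt = 5e-4, seed = 1, x0 = 5)
  expect_lt(max(abs(g - 5)), 1e-4)

  # single harmonic well: stationary law is the closed-form Gaussian
  pot <- potential_spec(5, 2, 0.7)
  g <- simulate_langevin_gap(pot, 4e6, dt = 5e-4, seed = 2, x0 = 5,
                             stride = 100L)
  g <- g[-(1:500)]  # discard equilibration
  ks <- max(abs(stats::ecdf(g)(sort(g)) - stats::pnorm(sort(g), 5, 0.7)))
  expect_lt(ks, 0.05)

  # default three wells: a 2 us run visits every well
  sys <- default_loop_system()
  g3 <- simulate_langevin_gap(sys$potential, 4e6, dt = 5e-4, seed = 3,
                              x0 = 8.5, stride = 10L)
  wells <- apply(abs(outer(g3, sys$potential$centers, `-`)), 1, which.min)
  expect_setequal(unique(wells), 1:3)

  # reproducibility and divergence guard (drift toward the well at 5
  # crosses the tight |g| bound)
  a <- simulate_langevin_gap(pot, 1000, seed = 9)
  b <- simulate_langevin_gap(pot, 1000, seed = 9)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(simulate_langevin_gap(pot, 2e4, dt = 5e-4, seed = 1,
                                     x0 = 0, bound = 2),
               "smaller dt")
})

test_that("loop embedding is a rigid translation plus jitter", {
  spec0 <- loop_model_spec(jitter_sd = 0)

  # constant 10 A gap: min inter-loop distance is exactly 10 (zero baseline)
  tr <- embed_loop_frames(rep(10, 3), spec0)
  d <- min_group_distance(frame_coords(tr, 1), tr$groups, "SEL", "LEL")
  expect_equal(d, 10, tolerance = 1e-12)

  # identical frames at constant gap
  expect_equal(rmsd(frame_coords(tr, 1), frame_coords(tr, 2)), 0,
               tolerance = 1e-9)

  # affine, strictly increasing gap -> distance map
  gs <- c(2, 5, 8, 12, 20)
  tr2 <- embed_loop_frames(gs, spec0)
  ds <- vapply(seq_along(gs), function(i) {
    min_group_distance(frame_coords(tr2, i), tr2$groups, "SEL", "LEL")
  }, numeric(1))
  expect_equal(ds, gs, tolerance = 1e-12)

  # jittered frames at two gap levels 4 A apart separate linearly in
  # kernel-feature space (nearest-centroid check)
  spec <- loop_model_spec(jitter_sd = 0.2)
  trA <- embed_loop_frames(rep(6, 30), spec, seed = 1)
  trB <- embed_loop_frames(rep(10, 30), spec, seed = 2)
  refs <- list(frame_coords(trA, 1), frame_coords(trB, 1))
  F <- rmsd_kernel_features(list(trA, trB), refs, sigma = 0.5)
  lab <- brute_assign(F, rbind(colMeans(F[1:30, ]), colMeans(F[31:60, ])))
  expect_identical(as.integer(lab), rep(1:2, each = 30))

  # seed determinism of the full surrogate
  sys <- default_loop_system()
  t1 <- simulate_loop_trajectory(sys, 50, seed = 5)
  t2 <- simulate_loop_trajectory(sys, 50, seed = 5)
  expect_identical(t1$coords, t2$coords)
})

test_that("default surrogate has three wells and validated reference kinetics", {
  sys <- default_loop_system()
  expect_length(sys$potential$centers, 3L)
  ts <- sys$ground_truth$timescales
  expect_true(all(is.finite(ts)))
  expect_true(all(diff(ts) <= 0))
  expect_equal(sum(sys$ground_truth$populations), 1, tolerance = 1e-12)
  Tgt <- sys$ground_truth$transition_matrix
  expect_equal(rowSums(Tgt), rep(1, 3), tolerance = 1e-10)

  # brute-force run vs the stored reference: slowest relaxation within 20%
  g <- simulate_langevin_gap(sys$potential, 6e7, dt = sys$sim$dt, seed = 1,
                             x0 = 8.5, stride = sys$sim$frame_stride)
  t2 <- well_relaxation_estimate(g, sys$potential$centers,
                                 lag_frames = 200L,
                                 frame_dt = sys$sim$frame_dt)
  expect_lt(abs(t2 - ts[1]) / ts[1], 0.20)

  # long-run occupancies match the Boltzmann integral over each well's
  # nearest-center basin (computed directly from the potential)
  wells <- apply(abs(outer(g, sys$potential$centers, `-`)), 1, which.min)
  occ <- as.numeric(prop.table(table(factor(wells, levels = 1:3))))
  x <- seq(-1, 19, length.out = 4000)
  w <- exp(-potential_energy(sys$potential, x) / sys$potential$kT)
  basin <- apply(abs(outer(x, sys$potential$centers, `-`)), 1, which.min)
  pops <- as.numeric(tapply(w, basin, sum)) / sum(w)
  # occupancy standard error is set by the slow relaxation: roughly
  # sqrt(2 p q t2 / T_run) ~ 0.05 here, so test at a 3-sigma band
  expect_lt(max(abs(occ - pops)), 0.15)
  # and the closed-form mixture weights agree with the integral closely
  expect_lt(max(abs(pops - sys$ground_truth$populations)), 0.02)
})

test_that("potential spec validation and closed-form density", {
  expect_error(potential_spec(c(5, 4), c(1, 1), c(1, 1)), "increasing")
  expect_error(potential_spec(5, 1, 0), "widths")
  pot <- potential_spec(c(0, 6), c(1, 2), c(1, 0.5))
  x <- seq(-4, 10, length.out = 500)
  dens <- boltzmann_density(pot, x)
  # density integrates to 1 and is proportional to exp(-U/kT)
  expect_equal(sum(dens) * (x[2] - x[1]), 1, tolerance = 1e-3)
  u <- potential_energy(pot, x)
  ratio <- dens / exp(-u / pot$kT)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
})
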