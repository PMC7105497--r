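test_that("transition counting matches hand enumeration", {
  d <- c(1, 1, 2, 2, 1)
  C1 <- count_matrix(d, lag = 1)
  expect_equal(C1$counts, matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE))
  C2 <- count_matrix(d, lag = 2)
  expect_equal(C2$counts, matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE))

  # strided counting uses disjoint windows
  C3 <- count_matrix(d, lag = 2, mode = "strided")
  expect_equal(sum(C3$counts), 2)

  # separate trajectories never contribute the boundary pair
  Csep <- count_matrix(list(c(1, 1), c(2, 2)), lag = 1)
  Ccat <- count_matrix(c(1, 1, 2, 2), lag = 1)
  expect_equal(Ccat$counts - Csep$counts,
               matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))

  expect_error(count_matrix(c(1, 2), lag = 5), "longer than the lag")
})

test_that("connected-set trimming keeps the heaviest strong component", {
  # block diagonal 2 + 3 states, more counts in the 3-block
  C <- count_matrix(list(c(1, 2, 1, 2), c(3, 4, 5, 3, 4, 5, 3, 4)), lag = 1)
  Ct <- trim_to_connected(C)
  expect_equal(Ct$active_set, 3:5)
  expect_equal(dim(Ct$counts), c(3L, 3L))

  # fully connected matrix is unchanged
  Cf <- count_matrix(c(1, 2, 3, 1, 3, 2, 1), lag = 1)
  expect_equal(trim_to_connected(Cf)$active_set, 1:3)

  # a single self-counting state survives alone
  Cs <- count_matrix(c(1, 1, 1), lag = 1)
  expect_equal(trim_to_connected(Cs)$active_set, 1L)
})

test_that("transition-matrix estimators: row norm, detailed balance, likelihood", {
  C <- count_matrix(c(1, 1, 1, 2, 1, 2, 2), lag = 1)
  C$counts <- matrix(c(2, 2, 1, 1), 2, 2, byrow = TRUE)
  est <- transition_matrix(C, reversible = FALSE)
  expect_equal(est$T, matrix(0.5, 2, 2))

  # symmetric counts: reversible estimate equals plain row normalization
  Cs <- C; Cs$counts <- matrix(c(4, 2, 2, 6), 2, 2, byrow = TRUE)
  expect_equal(transition_matrix(Cs, reversible = TRUE)$T,
               Cs$counts / rowSums(Cs$counts), tolerance = 1e-9)

  # random connected count matrices: detailed balance to 1e-8 and a
  # likelihood at least that of the naive symmetrized estimator
  set.seed(6)
  for (i in 1:10) {
    Cm <- matrix(rpois(16, 8) + 1, 4, 4)
    Cr <- count_matrix(c(1, 2, 3, 4, 1), lag = 1); Cr$counts <- Cm
    Cr$active_set <- 1:4
    est <- transition_matrix(Cr, reversible = TRUE)
    db <- est$pi * est$T
    expect_lt(max(abs(db - t(db))), 1e-8)
    expect_equal(rowSums(est$T), rep(1, 4), tolerance = 1e-10)
    naive <- (Cm + t(Cm)) / rowSums(Cm + t(Cm))
    expect_gte(loglik_counts(est$T, Cm), loglik_counts(naive, Cm) - 1e-6)
  }
})

test_that("stationary distribution solves pi T = pi", {
  expect_equal(stationary_distribution(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)),
               c(0.5, 0.5), tolerance = 1e-10)
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(stationary_distribution(T2), c(2 / 3, 1 / 3),
               tolerance = 1e-10)
  set.seed(2)
  Tr <- matrix(runif(9) + 0.05, 3, 3); Tr <- Tr / rowSums(Tr)
  p <- stationary_distribution(Tr)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(as.vector(p %*% Tr), p, tolerance = 1e-10)
})

test_that("markov_model recovers a known generator with 1/sqrt(N) error decay", {
  Tt <- matrix(c(0.90, 0.05, 0.05,
                 0.05, 0.90, 0.05,
                 0.05, 0.05, 0.90), 3, 3, byrow = TRUE)
  err_at <- function(N, seed) {
    d <- as.integer(sample_discrete_chain(Tt, N, seed = seed))
    m <- markov_model(d, lag = 1, dt = 1, reversible = FALSE)
    max(abs(m$transition_matrix - Tt))
  }
  med <- vapply(c(1e3, 1e4, 1e5), function(N) {
    stats::median(vapply(1:5, function(s) err_at(N, 100 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  slope <- coef(lm(log(med) ~ log(c(1e3, 1e4, 1e5))))[[2]]
  expect_lt(abs(slope + 0.5), 0.2)
})

test_that("implied timescales follow the closed form and are lag-stable", {
  # constructed spectra: t2 grows monotonically as lambda2 -> 1
  mk <- function(l2) {
    m <- structure(list(eigenvalues = c(1, l2), lag_ns = 20),
                   class = "markov_model")
    timescales(m, 1)
  }
  expect_equal(mk(0.8), -20 / log(0.8), tolerance = 1e-12)
  expect_true(mk(0.9) < mk(0.99) && mk(0.99) < mk(0.999))

  # exactly Markovian data: t2 flat across lags within sampling error
  T2 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  dtr <- lapply(1:4, function(i) {
    as.integer(sample_discrete_chain(T2, 5e4, seed = i))
  })
  its <- implied_timescales(dtr, lags = c(1, 2, 5, 10), dt = 1, k_eigs = 1)
  t2s <- its$timescale_ns[its$index == 2]
  truth <- -1 / log(0.9)
  expect_true(all(abs(t2s - truth) / truth < 0.15))

  # complex/negative eigenvalues are flagged as NA, not dropped
  per <- matrix(c(0, 1, 1, 0), 2, 2)   # period-2 chain, lambda2 = -1
  dper <- rep(c(1L, 2L), 200)
  itp <- implied_timescales(list(dper), lags = 1, dt = 1, k_eigs = 1,
                            reversible = FALSE)
  expect_true(is.na(itp$timescale_ns[1]))
})

test_that("chapman-kolmogorov test separates Markovian from hidden-state data", {
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  dtr <- as.integer(sample_discrete_chain(T2, 1e5, seed = 3))
  ck <- ck_test(list(dtr), lag = 1, factors = c(2L, 3L), dt = 1)
  expect_true(all(ck$max_deviation < 0.02))

  # deterministic cycle: T^2 matches the lag-2 estimate exactly
  cyc <- rep(c(1L, 2L, 3L), 300)
  ckc <- ck_test(list(cyc), lag = 1, factors = 2L, dt = 1,
                 reversible = FALSE)
  expect_equal(ckc$max_deviation, 0, tolerance = 1e-12)

  # hidden 3-state chain observed as 2 states is non-Markovian: two hidden
  # states with very different exit rates share an observed label
  Th <- matrix(c(0.98, 0.02, 0.00,
                 0.02, 0.58, 0.40,
                 0.00, 0.40, 0.60), 3, 3, byrow = TRUE)
  hid <- as.integer(sample_discrete_chain(Th, 2e5, seed = 4))
  obs <- ifelse(hid <= 2L, 1L, 2L)
  ckh <- ck_test(list(obs), lag = 1, factors = 4L, dt = 1)
  expect_gt(ckh$max_deviation, 0.05)
})

test_that("metastable-state counting finds the spectral gap", {
  # three blocks weakly coupled at 1e-3
  B <- matrix(1e-3, 6, 6)
  B[1:2, 1:2] <- 0.5; B[3:4, 3:4] <- 0.5; B[5:6, 5:6] <- 0.5
  B <- B / rowSums(B)
  ev <- sort(Re(eigen(B, only.values = TRUE)$values), decreasing = TRUE)
  expect_gt(ev[3], 0.99)  # eigen-gap verified directly
  expect_lt(ev[4], 0.5)
  expect_equal(count_metastable(B), 3L)

  # near-identity single-well chain
  single <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  expect_equal(count_metastable(single), 1L)
  expect_equal(count_metastable(matrix(1, 1, 1)), 1L)
})

test_that("model methods: coef, predict, simulate, summary", {
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  d <- as.integer(sample_discrete_chain(T2, 5e4, seed = 5))
  m <- markov_model(d, lag = 1, dt = 20)
  expect_equal(dim(coef(m)), c(2L, 2L))
  expect_equal(sum(predict(m, from = 1L, n_lags = 3)), 1, tolerance = 1e-12)
  expect_equal(predict(m, n_lags = 5), m$stationary_distribution,
               tolerance = 1e-8)
  s1 <- simulate(m, nsim = 100, seed = 1)
  s2 <- simulate(m, nsim = 100, seed = 1)
  expect_identical(as.integer(s1), as.integer(s2))
  sm <- summary(m)
  expect_equal(sm$n_states, 2L)
  expect_equal(sm$lag_ns, 20)
})

test_that("trajectory reconstruction has the right span and statistics", {
  Tt <- matrix(c(0.90, 0.05, 0.05,
                 0.05, 0.90, 0.05,
                 0.05, 0.05, 0.90), 3, 3, byrow = TRUE)
  d <- as.integer(sample_discrete_chain(Tt, 2e4, seed = 2))
  m <- markov_model(d, lag = 1, dt = 20)   # 20 ns lag
  fidx <- build_frame_index(list(d), m)

  # 5000 steps at a 20 ns lag span 100 us
  rec <- reconstruct_trajectory(m, fidx, 5000, seed = 1)
  expect_equal(rec$span_ns, 1e5)
  expect_equal(rec$times_ns[2] - rec$times_ns[1], 20)

  # every emitted frame belongs to the sampled state
  expect_true(all(d[rec$frames] == m$active_set[rec$states]))

  # absorbing chain emits only frames of the start state
  mabs <- m
  mabs$transition_matrix <- diag(3)
  rabs <- reconstruct_trajectory(mabs, fidx, 50, seed = 3, start = 1L)
  expect_true(all(rabs$states == 1L))

  # chain transition frequencies match T within 3 binomial standard errors
  long <- reconstruct_trajectory(m, fidx, 1e5, seed = 4)
  st <- long$states
  for (i in 1:3) {
    ni <- sum(st[-length(st)] == i)
    for (j in 1:3) {
      phat <- sum(st[-length(st)] == i & st[-1] == j) / ni
      p <- m$transition_matrix[i, j]
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / ni) + 1e-6)
    }
  }

  # a state without stored frames is refused up front
  expect_error(reconstruct_trajectory(m, list(1:3, integer(0), 4:5), 10),
               "without stored frames")
})
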