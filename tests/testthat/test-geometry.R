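test_that("kabsch superposition is exact on rigid motions", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)

  s0 <- kabsch_superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  for (i in 1:5) {
    R <- rand_rotation()
    shift <- rnorm(3, sd = 5)
    Y <- sweep(X %*% t(R), 2, shift, `+`)
    s <- kabsch_superpose(X, Y)
    expect_lt(s$rmsd, 1e-10)
    expect_equal(s$rotation, R, tolerance = 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
})

test_that("kabsch rmsd matches the quaternion oracle", {
  set.seed(7)
  for (i in 1:20) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
    expect_equal(rmsd(X, Y), quat_rmsd(X, Y), tolerance = 1e-9)
  }
  # compiled batch path agrees too
  tr <- trajectory(array(rnorm(5 * 10 * 3), dim = c(5, 10, 3)),
                   groups = rep("a", 10))
  D <- rmsd_matrix(tr)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j], quat_rmsd(frame_coords(tr, i), frame_coords(tr, j)),
                 tolerance = 1e-9)
  }
})

test_that("degenerate point sets are rejected, never reflected", {
  X <- matrix(rnorm(6), 2, 3)
  expect_error(kabsch_superpose(X, X), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("rmsd contracts: symmetry, displacement formula, minimization", {
  set.seed(3)
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(24), 8, 3)
  expect_equal(rmsd(X, Y), rmsd(Y, X), tolerance = 1e-9)
  expect_equal(rmsd(X, Y, superpose = FALSE), rmsd(Y, X, superpose = FALSE),
               tolerance = 1e-12)

  # one bead displaced by delta along an axis, no superposition: delta/sqrt(N)
  delta <- 0.7
  Y2 <- X; Y2[3, 1] <- Y2[3, 1] + delta
  expect_equal(rmsd(X, Y2, superpose = FALSE), delta / sqrt(8),
               tolerance = 1e-12)

  # minimized rmsd never exceeds the unsuperposed one
  for (i in 1:10) {
    A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(15), 5, 3)
    expect_lte(rmsd(A, B), rmsd(A, B, superpose = FALSE) + 1e-12)
  }

  # triangle bound for the unsuperposed metric
  for (i in 1:10) {
    A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(15), 5, 3)
    C <- matrix(rnorm(15), 5, 3)
    expect_lte(rmsd(A, C, superpose = FALSE),
               rmsd(A, B, superpose = FALSE) + rmsd(B, C, superpose = FALSE) + 1e-12)
  }
})

test_that("min_group_distance equals the exhaustive pair minimum", {
  frame <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(min_group_distance(frame, c("A", "B"), "A", "B"), 5.0)

  frame2 <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(min_group_distance(frame2, c("A", "B"), "A", "B"), 0)

  set.seed(5)
  pts <- matrix(rnorm(40 * 3, sd = 4), 40, 3)
  tags <- rep(c("A", "B"), each = 20)
  expect_equal(min_group_distance(pts, tags, "A", "B"),
               brute_min_dist(pts[1:20, ], pts[21:40, ]), tolerance = 1e-12)

  expect_error(min_group_distance(frame, c("A", "B"), "A", "C"), "'C'")
})

test_that("contact switching function: values, limit and errors", {
  p <- contact_params()
  expect_equal(contact(0, p), 1.0)
  # removable singularity at d0: analytic limit, cross-checked by evaluating
  # the rational form just off the cutoff
  expect_equal(contact(8.0, p), 0.5, tolerance = 1e-12)
  raw <- function(d) (1 - (d / 8)^6) / (1 - (d / 8)^12)
  expect_equal(raw(8 - 1e-6), 0.5, tolerance = 1e-6)
  expect_equal(raw(8 + 1e-6), 0.5, tolerance = 1e-6)
  # d = 2 d0: (d/d0)^6 = 64 -> (1-64)/(1-4096) = 1/65
  expect_equal(contact(16, p), 1 / 65, tolerance = 1e-12)
  expect_equal(raw(16), 1 / 65, tolerance = 1e-12)

  expect_error(contact(-1, p), "non-negative")
  expect_error(contact_params(d0 = 0), "d0")
  expect_error(contact_params(n = 6, m = 6), "0 < n < m")
})

test_that("contact is strictly decreasing, bounded and matches 1/(1+r^n)", {
  p <- contact_params()
  d <- seq(0, 40, length.out = 5000)
  v <- contact(d, p)
  expect_true(all(diff(v) <= 0))
  # strictly decreasing wherever (d/d0)^n is resolvable in double precision
  vs <- v[d >= 1]
  expect_true(all(diff(vs) < 0))
  expect_true(all(v > 0 & v <= 1))
  expect_lt(max(abs(v - 1 / (1 + (d / 8)^6))), 1e-12)
  # continuity across the cutoff
  dd <- seq(8 - 1e-4, 8 + 1e-4, length.out = 201)
  expect_lt(max(abs(diff(contact(dd, p)))), 1e-6)
  # exponents without m = 2n still hit the n/m limit at the cutoff
  p2 <- contact_params(d0 = 5, n = 4, m = 10)
  expect_equal(contact(5, p2), 0.4, tolerance = 1e-12)
})
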