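test_that("adaptive_round returns in-pool frames nearest the chosen centers", {
  sys <- default_loop_system()
  pool <- lapply(1:2, function(i) {
    simulate_loop_trajectory(sys, 60, seed = i, x0 = c(4, 14)[i])
  })
  cfg <- adaptive_config(pca_dims = 4, n_clusters = 12, n_restarts = 5,
                         restart_frames = 20, seed = 3)
  picks <- adaptive_round(pool, cfg)
  expect_equal(nrow(picks), 5L)
  expect_equal(anyDuplicated(picks$cluster), 0L)

  # verify each returned frame is the in-cluster argmin by brute force
  F <- position_features(pool)
  red <- pca_reduce(F, 4)
  disc <- kmeans_discretize(red$scores, 12, seed = cfg$seed)
  for (r in seq_len(nrow(picks))) {
    cl <- picks$cluster[r]
    members <- which(disc$labels == cl)
    d <- apply(red$scores[members, , drop = FALSE], 1, function(x) {
      sum((x - disc$centers[cl, ])^2)
    })
    expect_equal(picks$pool_row[r], members[which.min(d)])
  }

  # returned coordinates are actual pool members
  frames <- attr(picks, "frames")
  pc <- loopmsm:::pool_cube(pool)
  for (r in seq_len(nrow(picks))) {
    expect_equal(frames[[r]], matrix(pc$cube[, , picks$pool_row[r]], ncol = 3))
  }

  # determinism
  picks2 <- adaptive_round(pool, cfg)
  expect_identical(picks$pool_row, picks2$pool_row)

  expect_error(adaptive_round(pool, adaptive_config(n_clusters = 1000,
                                                    n_restarts = 10)),
               "at least")
})

test_that("every frame is selected when clusters = restarts = pool size", {
  spec <- loop_model_spec(jitter_sd = 0.3)
  tr <- embed_loop_frames(seq(3, 15, length.out = 12), spec, seed = 2)
  cfg <- adaptive_config(pca_dims = 3, n_clusters = 12, n_restarts = 12,
                         restart_frames = 5, seed = 1)
  picks <- adaptive_round(list(tr), cfg)
  expect_setequal(picks$pool_row, 1:12)
})

test_that("adaptive campaign bookkeeping: growth, provenance, determinism", {
  sys <- default_loop_system()
  cfg <- adaptive_config(pca_dims = 3, n_clusters = 20, n_restarts = 4,
                         restart_frames = 30, seed = 1)

  # zero rounds: pool is exactly the initial batch
  c0 <- run_adaptive_campaign(sys, n_initial = 3, initial_frames = 40,
                              rounds = 0, cfg = cfg, seed = 2)
  expect_length(c0$pool, 3L)
  expect_true(all(c0$log$round == 0L))

  c1 <- run_adaptive_campaign(sys, n_initial = 3, initial_frames = 40,
                              rounds = 2, cfg = cfg, seed = 2)
  expect_length(c1$pool, 3L + 2L * 4L)
  # pool grows monotonically and initial trajectories are untouched
  for (i in 1:3) expect_identical(c1$pool[[i]]$coords, c0$pool[[i]]$coords)

  # provenance: non-initial rows name an existing earlier trajectory, and
  # the parent-of relation is acyclic (parents always precede children)
  lg <- c1$log
  kids <- which(lg$round > 0)
  expect_true(all(is.finite(lg$parent_traj[kids])))
  for (k in kids) {
    expect_lt(lg$parent_traj[k], k)
    parent_len <- lg$n_frames[lg$parent_traj[k]]
    expect_lte(lg$parent_frame[k], parent_len)
  }

  # full campaign determinism under the master seed
  c2 <- run_adaptive_campaign(sys, n_initial = 3, initial_frames = 40,
                              rounds = 2, cfg = cfg, seed = 2)
  expect_identical(c1$log, c2$log)
  expect_identical(c1$pool[[length(c1$pool)]]$coords,
                   c2$pool[[length(c2$pool)]]$coords)
})

test_that("adaptive restarts match single-run well coverage on a fixed budget", {
  # same total frame budget: 5 x 100 initial + 8 x 50 restarts vs one 900-
  # frame run; adaptive should discover at least as many wells almost always
  sys <- default_loop_system()
  cfg <- adaptive_config(pca_dims = 3, n_clusters = 25, n_restarts = 8,
                         restart_frames = 50, seed = 1)
  wells_of <- function(gaps) {
    length(unique(apply(abs(outer(gaps, sys$potential$centers, `-`)), 1,
                        which.min)))
  }
  score <- vapply(1:10, function(s) {
    camp <- run_adaptive_campaign(sys, n_initial = 5, initial_frames = 100,
                                  rounds = 1, cfg = cfg, seed = s)
    g_ad <- unlist(lapply(camp$pool, function(t) attr(t, "gaps")))
    single <- simulate_loop_trajectory(sys, 900, seed = 2000 + s, x0 = 4)
    wells_of(g_ad) >= wells_of(attr(single, "gaps"))
  }, logical(1))
  expect_gte(sum(score), 8L)
})
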