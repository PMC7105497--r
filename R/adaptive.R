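#' Adaptive-sampling configuration
#'
#' Parameters of one cluster-restart round. The production-scale defaults
#' are PCA to 15 dimensions, 2000 k-means clusters, 100 random restarts and
#' 100 ns (1000-frame) restart runs; `adaptive_config_test()` ships a
#' scaled-down variant for desk-scale work.
#'
#' @param pca_dims PCA dimensionality of the positional features.
#' @param n_clusters k-means cluster count.
#' @param n_restarts clusters sampled (without replacement) for restarts;
#'   must not exceed `n_clusters`.
#' @param restart_frames length of each restart run in frames (0.1 ns each;
#'   1000 frames = 100 ns).
#' @param seed integer master seed.
#' @return A list of class `"adaptive_config"`.
#' @export
adaptive_config <- function(pca_dims = 15L, n_clusters = 2000L,
                            n_restarts = 100L, restart_frames = 1000L,
                            seed = 1L) {
  if (n_restarts > n_clusters) stop("n_restarts must be <= n_clusters")
  if (any(c(pca_dims, n_clusters, n_restarts, restart_frames) < 1)) {
    stop("all counts must be >= 1")
  }
  structure(list(pca_dims = as.integer(pca_dims),
                 n_clusters = as.integer(n_clusters),
                 n_restarts = as.integer(n_restarts),
                 restart_frames = as.integer(restart_frames),
                 seed = as.integer(seed)),
            class = "adaptive_config")
}

#' @rdname adaptive_config
#' @export
adaptive_config_test <- function(pca_dims = 5L, n_clusters = 50L,
                                 n_restarts = 10L, restart_frames = 200L,
                                 seed = 1L) {
  adaptive_config(pca_dims, n_clusters, n_restarts, restart_frames, seed)
}

#' Select restart frames by cluster-center proximity
#'
#' One adaptive-sampling round over an existing trajectory pool: superposed
#' positional features, PCA reduction, k-means clustering, uniform sampling
#' of `n_restarts` distinct clusters, and for each sampled cluster the pool
#' frame nearest (Euclidean, in reduced feature space) to the cluster
#' center. Restart frames are always actual pool members.
#'
#' @param pool list of trajectories.
#' @param cfg an [adaptive_config()].
#' @return data.frame with one row per restart: `cluster`, `traj`, `frame`
#'   (pool provenance) and `pool_row`; the frame coordinates are attached
#'   as attribute `"frames"` (list of matrices).
#' @export
adaptive_round <- function(pool, cfg = adaptive_config()) {
  stopifnot(inherits(cfg, "adaptive_config"))
  pc <- pool_cube(pool)
  n <- dim(pc$cube)[3]
  if (n < cfg$n_clusters) {
    stop("pool has ", n, " frames; need at least n_clusters = ",
         cfg$n_clusters)
  }
  F <- position_features(pool)
  red <- pca_reduce(F, min(cfg$pca_dims, ncol(F)))
  disc <- kmeans_discretize(red$scores, cfg$n_clusters, seed = cfg$seed)
  picks <- with_seed(cfg$seed + 1L, function() {
    sort(sample.int(cfg$n_clusters, cfg$n_restarts, replace = FALSE))
  })
  rows <- vapply(picks, function(cl) {
    members <- which(disc$labels == cl)
    d2 <- dist2_to_centers(red$scores[members, , drop = FALSE],
                           disc$centers[cl, , drop = FALSE])
    members[which.min(d2)]
  }, integer(1))
  out <- data.frame(cluster = picks,
                    traj = pc$prov$traj[rows],
                    frame = pc$prov$frame[rows],
                    pool_row = rows)
  attr(out, "frames") <- lapply(rows, function(i) {
    matrix(pc$cube[, , i], ncol = 3L)
  })
  out
}

#' Run an adaptive-sampling campaign on the synthetic loop system
#'
#' Alternates simulation and cluster-restart selection: an initial batch of
#' trajectories is simulated, then each round clusters the accumulated pool
#' ([adaptive_round()]) and restarts short runs from the selected frames
#' with fresh noise (the overdamped analogue of re-drawing Maxwell
#' velocities). The pool grows monotonically and every trajectory carries
#' provenance (round, parent trajectory/frame, seed). Round seeds derive
#' from the master seed by a fixed counter scheme
#' (`seed * 1000 + round * 100 + trajectory`), keeping every value well
#' below 2^31.
#'
#' Restart gaps are recovered from the selected frame as the minimum
#' SEL-LEL distance (exact up to jitter, since the default embedding has a
#' zero baseline offset).
#'
#' @param system a [default_loop_system()].
#' @param n_initial number of initial trajectories.
#' @param initial_frames frames per initial trajectory.
#' @param rounds number of adaptive rounds (0 = plain batch simulation).
#' @param cfg an [adaptive_config()].
#' @param seed master seed.
#' @return A list of class `"adaptive_campaign"`: `pool` (list of
#'   trajectories) and `log` (data.frame with one row per trajectory:
#'   round, parent_traj, parent_frame, seed, n_frames).
#' @export
run_adaptive_campaign <- function(system, n_initial = 5L,
                                  initial_frames = 500L, rounds = 1L,
                                  cfg = adaptive_config_test(),
                                  seed = 1L) {
  stopifnot(inherits(system, "loop_system"))
  pool <- list()
  log <- data.frame(round = integer(), parent_traj = integer(),
                    parent_frame = integer(), seed = integer(),
                    n_frames = integer())
  camp_seed <- function(r, j) {
    as.integer((as.numeric(seed) * 1000 + r * 100 + j) %% 2147483647)
  }
  for (i in seq_len(n_initial)) {
    s <- camp_seed(0L, i)
    pool[[length(pool) + 1L]] <-
      simulate_loop_trajectory(system, initial_frames, seed = s,
                               id = sprintf("r0_t%d", i))
    log <- rbind(log, data.frame(round = 0L, parent_traj = NA_integer_,
                                 parent_frame = NA_integer_, seed = s,
                                 n_frames = initial_frames))
  }
  for (r in seq_len(rounds)) {
    round_cfg <- cfg
    round_cfg$seed <- camp_seed(r, 0L)
    picks <- tryCatch(adaptive_round(pool, round_cfg),
                      error = function(e) {
                        warning("adaptive round ", r, " aborted: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
    if (is.null(picks)) break
    frames <- attr(picks, "frames")
    for (j in seq_len(nrow(picks))) {
      s <- camp_seed(r, j)
      g0 <- min_group_distance(frames[[j]], pool[[1]]$groups, "SEL", "LEL")
      traj <- tryCatch(
        simulate_loop_trajectory(system, cfg$restart_frames, seed = s,
                                 x0 = g0,
                                 id = sprintf("r%d_t%d", r, j)),
        error = function(e) {
          warning("restart ", j, " in round ", r, " failed: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(traj)) next
      pool[[length(pool) + 1L]] <- traj
      log <- rbind(log, data.frame(round = r, parent_traj = picks$traj[j],
                                   parent_frame = picks$frame[j], seed = s,
                                   n_frames = cfg$restart_frames))
    }
  }
  structure(list(pool = pool, log = log), class = "adaptive_campaign")
}

#' @export
print.adaptive_campaign <- function(x, ...) {
  cat("<adaptive_campaign>", length(x$pool), "trajectories,",
      sum(x$log$n_frames), "frames,", max(x$log$round), "round(s)\n")
  invisible(x)
}
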