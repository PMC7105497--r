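#' Write a trajectory to XYZ or multi-model PDB
#'
#' XYZ writes one model per frame with the element column reused as the
#' group tag (full tags round-trip). PDB writes MODEL/ENDMDL blocks with
#' the group tag in the chain-ID column (first character) and residue-name
#' column (first three characters); coordinates are written at the format's
#' standard precision (XYZ: 6 decimals, PDB: 3 decimals) and round-trip
#' exactly at that precision.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"xyz"` or `"pdb"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb"))
  nb <- dim(traj$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (i in seq_len(n_frames(traj))) {
      writeLines(c(as.character(nb),
                   sprintf("frame %d dt_ns %g", i, traj$dt)), con)
      writeLines(sprintf("%s %12.6f %12.6f %12.6f", traj$groups,
                         traj$coords[i, , 1], traj$coords[i, , 2],
                         traj$coords[i, , 3]), con)
    }
  } else {
    res <- toupper(substr(traj$groups, 1, 3))
    ch <- toupper(substr(traj$groups, 1, 1))
    for (i in seq_len(n_frames(traj))) {
      writeLines(sprintf("MODEL %8d", i), con)
      writeLines(sprintf(
        "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(nb), res, ch, seq_len(nb),
        traj$coords[i, , 1], traj$coords[i, , 2], traj$coords[i, , 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read a trajectory from XYZ or multi-model PDB
#'
#' Inverse of [write_trajectory()]. Inconsistent bead counts across frames
#' and malformed coordinate fields raise errors citing the frame or line
#' number.
#'
#' @param path input file.
#' @param format `"xyz"` or `"pdb"` (default: from the extension).
#' @param dt frame time step in ns to attach (XYZ frames record it in the
#'   comment line; default 0.1 when absent).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = NULL, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb"))
  lines <- readLines(path)
  if (format == "xyz") {
    frames <- list(); groups <- NULL; i <- 1L; fr <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      nb <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(nb)) stop("line ", i, ": expected a bead count")
      fr <- fr + 1L
      comment <- lines[i + 1L]
      if (is.null(dt)) {
        m <- regmatches(comment, regexec("dt_ns ([0-9.eE+-]+)", comment))[[1]]
        if (length(m) == 2L) dt <- as.numeric(m[2])
      }
      block <- lines[(i + 2L):(i + 1L + nb)]
      parts <- strsplit(trimws(block), "\\s+")
      tags <- vapply(parts, `[`, "", 1L)
      xyz <- t(vapply(seq_along(parts), function(j) {
        v <- suppressWarnings(as.numeric(parts[[j]][2:4]))
        if (anyNA(v)) stop("line ", i + 1L + j,
                           ": malformed coordinate field")
        v
      }, numeric(3)))
      if (is.null(groups)) groups <- tags
      else if (length(tags) != length(groups)) {
        stop("frame ", fr, ": bead count ", length(tags),
             " differs from frame 1 (", length(groups), ")")
      }
      frames[[fr]] <- xyz
      i <- i + 2L + nb
    }
  } else {
    frames <- list(); groups <- NULL; cur <- NULL; tags <- NULL; fr <- 0L
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, "MODEL")) {
        cur <- list(); tags <- character(0)
      } else if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) {
        x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
        y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
        z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
        if (anyNA(c(x, y, z))) stop("line ", i,
                                    ": malformed coordinate field")
        cur[[length(cur) + 1L]] <- c(x, y, z)
        tags <- c(tags, trimws(substr(ln, 18, 20)))
      } else if (startsWith(ln, "ENDMDL")) {
        fr <- fr + 1L
        if (is.null(groups)) groups <- tags
        else if (length(tags) != length(groups)) {
          stop("frame ", fr, ": bead count ", length(tags),
               " differs from frame 1 (", length(groups), ")")
        }
        frames[[fr]] <- do.call(rbind, cur)
        cur <- NULL
      }
    }
    if (is.null(dt)) dt <- 0.1
  }
  if (!length(frames)) stop("no frames found in ", path)
  coords <- array(0, dim = c(length(frames), length(groups), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, groups, dt = if (is.null(dt)) 0.1 else dt)
}

#' Write/read discrete trajectories as CSV
#'
#' One row per frame with columns `traj`, `frame`, `state` and a header.
#'
#' @param dtrajs list of integer label vectors.
#' @param path CSV file.
#' @return `write_dtrajs`: `path` invisibly; `read_dtrajs`: list of
#'   integer vectors.
#' @export
write_dtrajs <- function(dtrajs, path) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  df <- data.frame(traj = rep(seq_along(dtrajs), lengths(dtrajs)),
                   frame = unlist(lapply(lengths(dtrajs), seq_len)),
                   state = unlist(dtrajs))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dtrajs
#' @export
read_dtrajs <- function(path) {
  df <- read.csv(path)
  lapply(split(df$state, df$traj), as.integer)
}

#' Default pipeline configuration
#'
#' All stage parameters with their production defaults: kernel width 0.5 A
#' and 50 reference structures, 500 microstates, a 20 ns lag, 3-fold GMRQ
#' with 5 eigenvalues, adaptive sampling at PCA 15 / 2000 clusters / 100
#' restarts of 100 ns, contact parameters 8.0 A / 6 / 12, and
#' reconstruction spans of 20 us, 100 us and 15 ms. `scale = "test"`
#' shrinks only the sampling sizes (trajectory counts/lengths, reference
#' and cluster counts) for desk-scale runs; physical parameters are
#' untouched.
#'
#' @param seed master seed.
#' @param scale `"paper"` or `"test"`.
#' @return Nested configuration list of class `"run_config"`.
#' @export
default_config <- function(seed = 1L, scale = c("paper", "test")) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = as.integer(seed),
    scale = scale,
    simulation = list(n_traj = 50L, n_frames = 2000L),
    featurize = list(n_refs = 50L, sigma = 0.5),
    cluster = list(k = 500L),
    msm = list(lag_ns = 20, reversible = TRUE),
    its = list(lags_ns = c(2, 5, 10, 20, 40), k_eigs = 2L),
    gmrq = list(n_folds = 3L, m_eigs = 5L),
    adaptive = list(pca_dims = 15L, n_clusters = 2000L, n_restarts = 100L,
                    restart_ns = 100),
    contact = list(d0 = 8.0, n = 6L, m = 12L),
    reconstruct = list(spans = c("20us", "100us", "15ms")),
    report = list(closed_min = 0.6, open_max = 0.2, n_bins = 50L)
  )
  if (scale == "test") {
    cfg$simulation <- list(n_traj = 12L, n_frames = 2000L)
    cfg$featurize$n_refs <- 12L
    cfg$cluster$k <- 40L
    cfg$adaptive <- list(pca_dims = 5L, n_clusters = 50L, n_restarts = 10L,
                         restart_ns = 20)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read/write a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; the parse -> serialize -> parse round trip is
#' the identity.
#'
#' @param path YAML file.
#' @param config a `"run_config"`.
#' @return `read_config`: a validated `"run_config"`; `write_config`:
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- unclass(default_config())
  check_keys <- function(x, tmpl, where) {
    extra <- setdiff(names(x), names(tmpl))
    if (length(extra)) {
      stop("unknown config key(s) under ", where, ": ",
           paste(extra, collapse = ", "))
    }
    for (nm in names(x)) {
      if (is.list(tmpl[[nm]]) && !is.null(names(tmpl[[nm]]))) {
        check_keys(x[[nm]], tmpl[[nm]], paste0(where, "$", nm))
      }
    }
  }
  check_keys(raw, template, "config")
  cfg <- utils::modifyList(template, raw)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# "20us" / "15ms" / "200ns" -> ns
parse_span_ns <- function(s) {
  m <- regexec("^([0-9.]+)\\s*(ns|us|ms)$", s)
  parts <- regmatches(s, m)[[1]]
  if (length(parts) != 3L) stop("cannot parse span '", s,
                                "'; use e.g. '20us', '15ms', '200ns'")
  as.numeric(parts[2]) * switch(parts[3], ns = 1, us = 1e3, ms = 1e6)
}

write_json_meta <- function(path, ...) {
  meta <- c(list(package = "loopmsm",
                 version = as.character(utils::packageVersion("loopmsm")),
                 r_version = as.character(getRversion())),
            list(...))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains every stage on the synthetic loop system: simulate trajectories,
#' select k-medoid references and compute RMSD-kernel features, discretize
#' by k-means, fit the Markov model at the configured lag, tabulate implied
#' timescales, reconstruct long pseudo-trajectories at the configured
#' spans, and report the contact time course, distribution and named-state
#' fractions. Every CSV artifact gets a JSON metadata sidecar (config,
#' seed, package version). The run is deterministic under a fixed config
#' and seed.
#'
#' @param config a `"run_config"` (default: [default_config()] at test
#'   scale).
#' @param outdir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param system the synthetic `loop_system` (default
#'   [default_loop_system()]).
#' @param quiet suppress stage messages (stages log to stderr).
#' @return A list of class `"pipeline_result"`: `trajs`, `refs`,
#'   `features`, `discretization`, `dtrajs`, `model`, `its`,
#'   `reconstructions` (named by span), `report` (metastable count,
#'   contact histogram, state fractions), `config`.
#' @export
run_pipeline <- function(config = default_config(scale = "test"),
                         outdir = NULL, system = default_loop_system(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[loopmsm] ", ...)
  seed <- config$seed
  frame_dt <- system$sim$frame_dt
  t0 <- proc.time()[3]

  say("simulate: ", config$simulation$n_traj, " x ",
      config$simulation$n_frames, " frames")
  wells <- system$potential$centers
  trajs <- lapply(seq_len(config$simulation$n_traj), function(i) {
    simulate_loop_trajectory(system, config$simulation$n_frames,
                             seed = derive_seed(seed, 1L, i),
                             x0 = wells[((i - 1L) %% length(wells)) + 1L],
                             id = sprintf("sim_t%d", i))
  })

  say("featurize: ", config$featurize$n_refs, " k-medoid references, sigma = ",
      config$featurize$sigma)
  refs <- select_references(trajs, k = config$featurize$n_refs,
                            seed = derive_seed(seed, 2L, 0L))
  F <- rmsd_kernel_features(trajs, refs, sigma = config$featurize$sigma)

  say("cluster: k-means k = ", config$cluster$k)
  disc <- kmeans_discretize(F, k = config$cluster$k,
                            seed = derive_seed(seed, 3L, 0L))
  nf <- vapply(trajs, n_frames, 1L)
  dtrajs <- split(disc$labels, rep(seq_along(trajs), nf))

  lag_steps <- max(1L, round(config$msm$lag_ns / frame_dt))
  say("msm: lag ", config$msm$lag_ns, " ns (", lag_steps, " steps)")
  model <- markov_model(dtrajs, lag = lag_steps, dt = frame_dt,
                        reversible = config$msm$reversible)

  say("implied timescales over ", length(config$its$lags_ns), " lags")
  its <- implied_timescales(dtrajs,
                            lags = pmax(1L, round(config$its$lags_ns / frame_dt)),
                            dt = frame_dt, k_eigs = config$its$k_eigs,
                            reversible = config$msm$reversible)

  cpar <- contact_params(config$contact$d0, config$contact$n,
                         config$contact$m)
  cvals <- pool_contact_values(trajs, params = cpar)
  fidx <- build_frame_index(dtrajs, model)
  recons <- list()
  for (sp in config$reconstruct$spans) {
    ns <- parse_span_ns(sp)
    n_steps <- max(2L, round(ns / model$lag_ns))
    say("reconstruct: ", sp, " (", n_steps, " steps)")
    rec <- reconstruct_trajectory(model, fidx, n_steps,
                                  seed = derive_seed(seed, 4L,
                                                     length(recons) + 1L))
    recons[[sp]] <- reconstructed_contact_series(rec, cvals, params = cpar)
  }

  thr <- state_thresholds(config$report$closed_min, config$report$open_max)
  longest <- recons[[length(recons)]]
  hist <- contact_distribution(longest, n_bins = config$report$n_bins)
  fracs <- prop.table(table(classify_states(longest, thr)))
  report <- list(n_metastable = count_metastable(model),
                 contact_histogram = hist,
                 state_fractions = fracs,
                 thresholds = thr)
  say(sprintf("done in %.1f s; %d model states, %d metastable",
              proc.time()[3] - t0, nrow(model$transition_matrix),
              report$n_metastable))

  res <- structure(list(trajs = trajs, refs = refs, features = F,
                        discretization = disc, dtrajs = dtrajs,
                        model = model, its = its,
                        reconstructions = recons, report = report,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_artifacts(res, outdir)
  res
}

derive_seed <- function(master, stage, item) {
  as.integer((as.numeric(master) * 997 + stage * 131071 + item) %%
               2147483647)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  trajectories:", length(x$trajs), "x",
      n_frames(x$trajs[[1]]), "frames\n")
  cat("  microstates:", x$discretization$k, "-> model states:",
      nrow(x$model$transition_matrix), "\n")
  cat("  metastable states:", x$report$n_metastable, "\n")
  cat("  state fractions:",
      paste(names(x$report$state_fractions),
            round(as.numeric(x$report$state_fractions), 3),
            collapse = ", "), "\n")
  invisible(x)
}

write_pipeline_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  p <- function(f) file.path(outdir, f)

  write_dtrajs(res$dtrajs, p("dtrajs.csv"))
  write.csv(as.data.frame(res$model$transition_matrix),
            p("transition_matrix.csv"), row.names = FALSE)
  write.csv(data.frame(state = res$model$active_set,
                       pi = res$model$stationary_distribution),
            p("stationary.csv"), row.names = FALSE)
  write.csv(as.data.frame(res$its), p("implied_timescales.csv"),
            row.names = FALSE)
  for (i in seq_along(res$reconstructions)) {
    nm <- names(res$reconstructions)[i]
    write.csv(res$reconstructions[[i]],
              p(sprintf("contact_timecourse_%s.csv", nm)),
              row.names = FALSE)
  }
  write.csv(as.data.frame(res$report$contact_histogram),
            p("contact_distribution.csv"), row.names = FALSE)
  write.csv(data.frame(state = names(res$report$state_fractions),
                       fraction = as.numeric(res$report$state_fractions)),
            p("state_fractions.csv"), row.names = FALSE)
  write_json_meta(p("metadata.json"),
                  config = unclass(cfg),
                  n_model_states = nrow(res$model$transition_matrix),
                  n_metastable = res$report$n_metastable,
                  thresholds = unclass(res$report$thresholds))
  invisible(outdir)
}
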