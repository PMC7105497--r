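#' Trajectory container
#'
#' A trajectory is an ordered set of frames of labelled 3-D bead coordinates
#' with a fixed time step between frames. Coordinates are in Angstrom, the
#' time step in nanoseconds. Each bead carries a group tag (e.g. `"SEL"`,
#' `"LEL"`, `"core"`) used by the contact observable and by group-wise
#' geometry.
#'
#' @param coords numeric array of dimension `n_frames x n_beads x 3`, or a
#'   single `n_beads x 3` matrix for a one-frame trajectory.
#' @param groups character vector of length `n_beads` with one tag per bead.
#' @param dt time between consecutive frames in ns (default 0.1).
#' @param id optional identifier carried through provenance records.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(coords, groups, dt = 0.1, id = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (length(groups) != dim(coords)[2]) {
    stop("length(groups) must equal the number of beads (", dim(coords)[2], ")")
  }
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive time step in ns")
  structure(list(coords = coords, groups = as.character(groups),
                 dt = dt, id = id),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[1]
}

#' Extract one frame as a coordinate matrix
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return `n_beads x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"), i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", n_frames(x), "frames,", dim(x$coords)[2], "beads,",
      "dt =", x$dt, "ns\n")
  cat("  groups:", paste(sprintf("%s(%d)", names(table(x$groups)),
                                 as.integer(table(x$groups))),
                         collapse = " "), "\n")
  if (!is.null(x$id)) cat("  id:", x$id, "\n")
  invisible(x)
}

#' @export
`[.trajectory` <- function(x, i) {
  trajectory(x$coords[i, , , drop = FALSE], x$groups, dt = x$dt, id = x$id)
}

# Stack all frames of a trajectory pool into one n_beads x 3 x total_frames
# cube (the layout the compiled RMSD routines use), plus provenance.
pool_cube <- function(pool) {
  if (inherits(pool, "trajectory")) pool <- list(pool)
  stopifnot(length(pool) >= 1, all(vapply(pool, inherits, TRUE, "trajectory")))
  nb <- vapply(pool, function(t) dim(t$coords)[2], 1L)
  if (length(unique(nb)) != 1L) stop("all trajectories must share a bead count")
  nf <- vapply(pool, n_frames, 1L)
  cube <- array(0, dim = c(nb[1], 3L, sum(nf)))
  prov <- data.frame(traj = rep(seq_along(pool), nf),
                     frame = unlist(lapply(nf, seq_len)))
  k <- 0L
  for (t in pool) {
    for (i in seq_len(n_frames(t))) {
      k <- k + 1L
      cube[, , k] <- t$coords[i, , ]
    }
  }
  list(cube = cube, prov = prov, groups = pool[[1]]$groups, dt = pool[[1]]$dt)
}
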