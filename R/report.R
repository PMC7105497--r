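#' Contact time course along a trajectory
#'
#' Per-frame contact value: the minimum inter-group distance between the
#' two loop groups pushed through the rational switching function. A value
#' near 1 means the loops are in contact (closed), near 0 far apart (open).
#'
#' @param traj a [trajectory()].
#' @param groupA,groupB group tags (defaults `"SEL"`, `"LEL"`).
#' @param params a [contact_params()].
#' @return data.frame of class `"contact_series"` with columns `time_ns`
#'   and `contact`; the parameters are attached as attribute `"params"`.
#' @export
contact_timecourse <- function(traj, groupA = "SEL", groupB = "LEL",
                               params = contact_params()) {
  stopifnot(inherits(traj, "trajectory"))
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    contact(min_group_distance(frame_coords(traj, i), traj$groups,
                               groupA, groupB), params)
  }, numeric(1))
  out <- data.frame(time_ns = (seq_len(n_frames(traj)) - 1) * traj$dt,
                    contact = vals)
  attr(out, "params") <- params
  class(out) <- c("contact_series", "data.frame")
  out
}

#' Per-frame contact values of a trajectory pool
#'
#' Convenience for reconstruction: computes the contact value of every
#' frame of the pool once, in pooled frame order, so reconstructed
#' trajectories can look contacts up by emitted frame position.
#'
#' @param pool list of trajectories.
#' @inheritParams contact_timecourse
#' @return Numeric vector, one value per pooled frame.
#' @export
pool_contact_values <- function(pool, groupA = "SEL", groupB = "LEL",
                                params = contact_params()) {
  if (inherits(pool, "trajectory")) pool <- list(pool)
  unlist(lapply(pool, function(t) {
    contact_timecourse(t, groupA, groupB, params)$contact
  }), use.names = FALSE)
}

#' Contact series of a reconstructed trajectory
#'
#' @param recon a [reconstruct_trajectory()] result.
#' @param contact_values per-pooled-frame contacts from
#'   [pool_contact_values()].
#' @param params the [contact_params()] used (metadata).
#' @return A `"contact_series"` data.frame on the reconstructed time axis
#'   (step index times the model lag).
#' @export
reconstructed_contact_series <- function(recon, contact_values,
                                         params = contact_params()) {
  stopifnot(inherits(recon, "reconstructed_trajectory"))
  out <- data.frame(time_ns = recon$times_ns,
                    contact = contact_values[recon$frames])
  attr(out, "params") <- params
  class(out) <- c("contact_series", "data.frame")
  out
}

#' @export
plot.contact_series <- function(x, ...) {
  t <- x$time_ns
  if (max(t) >= 1e6) { t <- t / 1e6; xl <- "time (ms)" }
  else if (max(t) >= 1e3) { t <- t / 1e3; xl <- "time (us)" }
  else xl <- "time (ns)"
  graphics::plot(t, x$contact, type = "l", ylim = c(0, 1),
                 xlab = xl, ylab = "SEL-LEL contact", ...)
  invisible(x)
}

#' Contact-value distribution
#'
#' Density-normalized histogram of a contact series on [0, 1]
#' (`sum(density * width) = 1`). A multimodal distribution reflects
#' metastable closed / semi-open / open populations.
#'
#' @param series a `"contact_series"` (or numeric vector of contacts).
#' @param n_bins number of equal bins on [0, 1].
#' @return data.frame of class `"contact_histogram"` with `bin_lo`,
#'   `bin_hi`, `mid`, `density`.
#' @export
contact_distribution <- function(series, n_bins = 50L) {
  v <- if (is.data.frame(series)) series$contact else as.numeric(series)
  if (!length(v)) stop("empty contact series")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  width <- diff(edges)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    mid = (edges[-1] + edges[-length(edges)]) / 2,
                    density = counts / (sum(counts) * width))
  class(out) <- c("contact_histogram", "data.frame")
  out
}

#' @export
plot.contact_histogram <- function(x, ...) {
  graphics::plot(x$mid, x$density, type = "h", lwd = 4,
                 xlab = "SEL-LEL contact", ylab = "density", ...)
  invisible(x)
}

#' Count modes of a contact distribution
#'
#' Kernel-smoothed mode counting: local maxima of a Gaussian kernel density
#' estimate of the contact values, keeping maxima above a fraction of the
#' global peak.
#'
#' @param series contact series or numeric vector.
#' @param bw kernel bandwidth (default 0.04 contact units).
#' @param min_height fraction of the tallest peak below which maxima are
#'   ignored.
#' @return Integer mode count.
#' @export
count_contact_modes <- function(series, bw = 0.04, min_height = 0.05) {
  v <- if (is.data.frame(series)) series$contact else as.numeric(series)
  d <- stats::density(v, bw = bw, from = -0.05, to = 1.05, n = 512)
  y <- d$y
  is_max <- y[2:511] > y[1:510] & y[2:511] >= y[3:512]
  sum(is_max & y[2:511] > min_height * max(y))
}

#' Named-state thresholds on the contact value
#'
#' Operational boundaries mapping a contact value to the named loop states:
#' closed when `contact >= closed_min`, open when `contact <= open_max`,
#' semi-open in between. The defaults (0.6 / 0.2) are this package's
#' operationalization — the named states themselves are structural, and no
#' canonical numeric boundary exists.
#'
#' @param closed_min minimum contact of the closed state.
#' @param open_max maximum contact of the open state.
#' @return A list of class `"state_thresholds"`.
#' @export
state_thresholds <- function(closed_min = 0.6, open_max = 0.2) {
  if (!(0 < open_max && open_max < closed_min && closed_min < 1)) {
    stop("thresholds must satisfy 0 < open_max < closed_min < 1")
  }
  structure(list(closed_min = closed_min, open_max = open_max),
            class = "state_thresholds")
}

#' Classify contact values into named loop states
#'
#' Deterministic per-value classification; boundary values fall into the
#' extreme classes (`>= closed_min` is closed, `<= open_max` is open).
#'
#' @param series contact series or numeric vector.
#' @param thr a [state_thresholds()].
#' @return Factor with levels `closed`, `semi-open`, `open`.
#' @export
classify_states <- function(series, thr = state_thresholds()) {
  stopifnot(inherits(thr, "state_thresholds"))
  v <- if (is.data.frame(series)) series$contact else as.numeric(series)
  out <- ifelse(v >= thr$closed_min, "closed",
                ifelse(v <= thr$open_max, "open", "semi-open"))
  factor(out, levels = c("closed", "semi-open", "open"))
}
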