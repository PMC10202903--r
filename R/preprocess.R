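#' Zero-phase low-pass Butterworth filter
#'
#' Filters x and y independently with a forward-backward (zero-phase-lag)
#' Butterworth low-pass. The signal is extended by odd reflection at both
#' ends before `signal::filtfilt` and trimmed afterwards, which removes the
#' edge transients of the bare forward-backward pass (a constant input is
#' returned unchanged).
#'
#' @param traj a [trajectory()].
#' @param cutoff cutoff frequency in Hz, strictly below Nyquist.
#' @param order Butterworth order (default 2).
#' @return a filtered [trajectory()] of the same length.
#' @export
lowpass_filter <- function(traj, cutoff = 7, order = 2) {
  validate_trajectory(traj)
  nyq <- traj$sample_rate / 2
  if (!(cutoff > 0 && cutoff < nyq)) {
    stop("cutoff must lie in (0, Nyquist = ", nyq, " Hz)")
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  s <- traj$samples
  n <- nrow(s)
  pad <- min(n - 1L, max(3L * order, ceiling(6 * traj$sample_rate / cutoff)))
  refl_filt <- function(v) {
    head_ext <- 2 * v[1] - v[(pad + 1):2]
    tail_ext <- 2 * v[n] - v[(n - 1):(n - pad)]
    out <- signal::filtfilt(bf, c(head_ext, v, tail_ext))
    out[(pad + 1):(pad + n)]
  }
  trajectory(s$t, refl_filt(s$x), refl_filt(s$y),
             subject_id = traj$subject_id, hand = traj$hand,
             speed = traj$speed, sample_rate = traj$sample_rate)
}

#' Finite-difference kinematics of a trajectory
#'
#' Velocities and accelerations by central differences on interior samples
#' and second-order one-sided differences at the two ends; tangential speed
#' is the Euclidean norm of the velocity.
#'
#' @param traj a uniformly sampled [trajectory()].
#' @return an object of class `kinematic_profile`: list with per-sample
#'   vectors `vx`, `vy`, `ax`, `ay`, `speed` (all aligned with the
#'   trajectory samples) plus `t` and `dt`.
#' @export
estimate_derivatives <- function(traj) {
  validate_trajectory(traj)
  s <- traj$samples
  if (nrow(s) < 3L) stop("need at least 3 samples to differentiate")
  dt <- 1 / traj$sample_rate
  vx <- fd_gradient(s$x, dt)
  vy <- fd_gradient(s$y, dt)
  ax <- fd_gradient(vx, dt)
  ay <- fd_gradient(vy, dt)
  structure(list(t = s$t, dt = dt, vx = vx, vy = vy, ax = ax, ay = ay,
                 speed = sqrt(vx^2 + vy^2)),
            class = "kinematic_profile")
}

# central differences, second-order one-sided at the ends
fd_gradient <- function(v, dt) {
  n <- length(v)
  g <- numeric(n)
  g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  g[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * dt)
  g[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * dt)
  g
}

#' Segment a continuous tracing into elliptical cycles
#'
#' Computes the centroid angle `theta(t) = atan2(y - ybar, x - xbar)`,
#' unwraps it, and accumulates `|d theta|`; a cycle boundary falls at the
#' sample nearest each crossing of a multiple of 2 pi. Direction-agnostic
#' (clockwise and counterclockwise tracings segment identically); a
#' trailing partial revolution is discarded.
#'
#' @param traj a [trajectory()] containing at least one full revolution
#'   about its centroid.
#' @param min_cycle_samples cycles spanning fewer samples are rejected.
#' @param revolution_tolerance fraction of a revolution by which the final
#'   cycle may fall short and still count; absorbs centroid drift and the
#'   sub-sample shortfall of the last boundary (default 2%).
#' @return a data.frame of class `cycle_set` with columns `start`, `end`
#'   (half-open 1-based sample index range `[start, end)`) and
#'   `cycle_index` (0-based).
#' @export
segment_cycles <- function(traj, min_cycle_samples = 16L,
                           revolution_tolerance = 0.02) {
  validate_trajectory(traj)
  s <- traj$samples
  th <- atan2(s$y - mean(s$y), s$x - mean(s$x))
  cum <- c(0, cumsum(abs(diff(signal::unwrap(th)))))
  total <- cum[length(cum)]
  n_full <- floor(total / (2 * pi) + revolution_tolerance)
  if (n_full < 1L) stop("no complete cycle: total angular excursion ",
                        signif(total, 4), " rad < 2 pi")
  bounds <- integer(n_full)
  for (k in seq_len(n_full)) {
    target <- 2 * pi * k
    i <- which(cum >= target)[1]
    if (is.na(i)) i <- length(cum)           # tolerated final shortfall
    # snap to the sample nearest the crossing
    if (i > 1 && (target - cum[i - 1]) < (cum[i] - target)) i <- i - 1L
    bounds[k] <- i
  }
  starts <- c(1L, bounds[-n_full])
  ends <- bounds
  short <- which(ends - starts < min_cycle_samples)
  if (length(short)) {
    stop("cycle ", short[1] - 1L, " spans fewer than ", min_cycle_samples,
         " samples")
  }
  structure(data.frame(start = starts, end = ends,
                       cycle_index = seq_len(n_full) - 1L),
            class = c("cycle_set", "data.frame"))
}

#' Apply the first/last cycle exclusion rule
#'
#' Drops the first `n_first` and last `n_last` cycles of a recording (the
#' defaults drop the first and the two last drawn ellipses, retaining 7 of
#' the task's 10).
#'
#' @param cycles a `cycle_set` from [segment_cycles()].
#' @param n_first,n_last cycles to drop at either end.
#' @param min_cycles minimum cycles that must remain.
#' @return the retained `cycle_set` rows.
#' @export
exclude_cycles <- function(cycles, n_first = 1L, n_last = 2L,
                           min_cycles = 2L) {
  if (n_first < 0 || n_last < 0) stop("exclusion counts must be >= 0")
  n <- nrow(cycles)
  kept <- n - n_first - n_last
  if (kept < min_cycles) {
    stop("too few cycles: ", n, " segmented, ", max(kept, 0),
         " would remain after excluding first ", n_first, " and last ",
         n_last, " (need >= ", min_cycles, ")")
  }
  out <- cycles[seq(n_first + 1L, n - n_last), , drop = FALSE]
  rownames(out) <- NULL
  out
}
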