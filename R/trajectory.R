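#' Pen trajectory objects
#'
#' A `trajectory` is the raw unit of analysis: a time-ordered sequence of
#' (t, x, y) pen samples labelled with subject, hand (dominant `"D"` or
#' non-dominant `"ND"`) and speed condition (`"S"` slow, `"N"` normal,
#' `"F"` fast). Positions are in cm, time in s.
#'
#' Invariants enforced by [validate_trajectory()]: at least 4 samples, all
#' values finite, `t` strictly increasing, and successive time gaps within
#' +/- 10% of `1 / sample_rate`. Irregularly sampled input should go through
#' [regularize_trajectory()] first (the file reader does this automatically).
#'
#' @param t,x,y numeric vectors of equal length: time (s) and position (cm).
#' @param subject_id opaque subject label.
#' @param hand `"D"` or `"ND"`.
#' @param speed `"S"`, `"N"` or `"F"`.
#' @param sample_rate nominal sampling rate in Hz.
#' @return An object of class `trajectory`: a list with elements
#'   `subject_id`, `hand`, `speed`, `sample_rate` and `samples`
#'   (a data.frame with columns `t`, `x`, `y`).
#' @examples
#' tr <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1)
#' tr
#' @export
trajectory <- function(t, x, y, subject_id = "anon", hand = c("D", "ND"),
                       speed = c("N", "S", "F"), sample_rate = 200) {
  hand <- match.arg(hand)
  speed <- match.arg(speed)
  obj <- structure(
    list(
      subject_id = as.character(subject_id),
      hand = hand,
      speed = speed,
      sample_rate = as.numeric(sample_rate),
      samples = data.frame(t = as.numeric(t), x = as.numeric(x),
                           y = as.numeric(y))
    ),
    class = "trajectory"
  )
  validate_trajectory(obj)
  obj
}

#' Validate a trajectory object
#'
#' Checks the `trajectory` invariants and fails with an informative error
#' naming the first offending sample where applicable.
#'
#' @param traj a [trajectory()] object.
#' @param gap_tolerance allowed relative deviation of successive time gaps
#'   from `1 / sample_rate` (default 0.1, i.e. 10%).
#' @return `traj`, invisibly, if valid.
#' @export
validate_trajectory <- function(traj, gap_tolerance = 0.1) {
  if (!inherits(traj, "trajectory")) stop("not a trajectory object")
  s <- traj$samples
  if (!all(c("t", "x", "y") %in% names(s))) stop("samples must have columns t, x, y")
  n <- nrow(s)
  if (n < 4L) stop("trajectory must have at least 4 samples, got ", n)
  for (col in c("t", "x", "y")) {
    bad <- which(!is.finite(s[[col]]))
    if (length(bad)) stop("non-finite ", col, " at sample ", bad[1])
  }
  dt <- diff(s$t)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop("t must be strictly increasing; violation at sample index ", bad[1] + 1L)
  }
  if (!is.finite(traj$sample_rate) || traj$sample_rate <= 0) {
    stop("sample_rate must be positive")
  }
  nominal <- 1 / traj$sample_rate
  bad <- which(abs(dt - nominal) > gap_tolerance * nominal)
  if (length(bad)) {
    stop("sampling gap at index ", bad[1] + 1L, " deviates more than ",
         round(100 * gap_tolerance), "% from 1/sample_rate; ",
         "use regularize_trajectory() first")
  }
  if (!traj$hand %in% c("D", "ND")) stop("hand must be 'D' or 'ND'")
  if (!traj$speed %in% c("S", "N", "F")) stop("speed must be 'S', 'N' or 'F'")
  invisible(traj)
}

#' Resample a trajectory to a uniform time grid
#'
#' Linearly interpolates x and y onto a uniform grid at `sample_rate`,
#' covering the recorded time span. Used for recordings with dropped samples
#' whose time gaps exceed the 10% tolerance.
#'
#' @param traj a `trajectory`-shaped object (invariants not required).
#' @param sample_rate target rate in Hz; defaults to the object's own rate.
#' @return a valid [trajectory()] with uniform sampling.
#' @export
regularize_trajectory <- function(traj, sample_rate = traj$sample_rate) {
  s <- traj$samples
  if (nrow(s) < 2L) stop("need at least 2 samples to resample")
  tt <- seq(s$t[1], s$t[nrow(s)], by = 1 / sample_rate)
  trajectory(
    t = tt,
    x = stats::approx(s$t, s$x, xout = tt, rule = 2)$y,
    y = stats::approx(s$t, s$y, xout = tt, rule = 2)$y,
    subject_id = traj$subject_id, hand = traj$hand, speed = traj$speed,
    sample_rate = sample_rate
  )
}

#' @export
print.trajectory <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<trajectory> subject %s, hand %s, speed %s\n  %d samples @ %g Hz, %.2f s, x [%.2f, %.2f] cm, y [%.2f, %.2f] cm\n",
    x$subject_id, x$hand, x$speed, nrow(s), x$sample_rate,
    s$t[nrow(s)] - s$t[1], min(s$x), max(s$x), min(s$y), max(s$y)
  ))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) x$samples

n_samples <- function(traj) nrow(traj$samples)
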