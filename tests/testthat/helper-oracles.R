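# Independent oracles used across the suite.

# Menger three-point curvature: 4 * area / (|AB| |BC| |CA|), evaluated on
# sample triples spaced `stride` apart. Independent of the derivative-based
# estimator in the package.
menger_curvature <- function(x, y, stride = 1L) {
  n <- length(x)
  i <- seq(1L + stride, n - stride)
  x1 <- x[i - stride]; y1 <- y[i - stride]
  x2 <- x[i]; y2 <- y[i]
  x3 <- x[i + stride]; y3 <- y[i + stride]
  area2 <- abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  d12 <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d23 <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
  d13 <- sqrt((x3 - x1)^2 + (y3 - y1)^2)
  list(index = i, C = 2 * area2 / (d12 * d23 * d13))
}

# closed-form curvature of the axis-aligned ellipse at parameter phi
ellipse_curvature_at <- function(a, b, phi) {
  a * b / (a^2 * sin(phi)^2 + b^2 * cos(phi)^2)^1.5
}

# quadrature perimeter of an ellipse, independent of pracma::ellipke
ellipse_perimeter_quadrature <- function(a, b) {
  stats::integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# balanced within-subject response table for ANOVA tests
make_factorial_table <- function(n_subjects, value_fun) {
  d <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   hand = c("D", "ND"), speed = c("S", "N", "F"),
                   stringsAsFactors = FALSE)
  d$value <- value_fun(d)
  d
}

# restrict a kinematic profile to one cycle's half-open sample range
slice_profile_for_test <- function(profile, cycle) {
  idx <- cycle$start:(cycle$end - 1L)
  structure(list(t = profile$t[idx], dt = profile$dt,
                 vx = profile$vx[idx], vy = profile$vy[idx],
                 ax = profile$ax[idx], ay = profile$ay[idx],
                 speed = profile$speed[idx]),
            class = "kinematic_profile")
}

write_temp_trajectory <- function(traj) {
  path <- tempfile(fileext = ".csv")
  write_trajectory_table(traj, path)
  path
}
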