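#' Per-cycle kinematic features
#'
#' Duration is the time from the cycle's first sample to the start of the
#' next cycle; peak velocity (max V, "vigor") and mean velocity are taken
#' over the cycle's tangential speed samples.
#'
#' @param cycle one row of a `cycle_set` (list or data.frame row with
#'   `start`, `end`).
#' @param profile a [estimate_derivatives()] result for the parent
#'   trajectory.
#' @return list with `duration` (s), `max_v`, `mean_v` (cm/s).
#' @export
kinematic_features <- function(cycle, profile) {
  n <- length(profile$t)
  i0 <- cycle$start
  i1 <- min(cycle$end, n)
  sp <- profile$speed[i0:(i1 - 1L)]
  list(duration = profile$t[i1] - profile$t[i0],
       max_v = max(sp), mean_v = mean(sp))
}

#' Curvature profile from derivatives
#'
#' Signed-magnitude discrete curvature `C = |vx ay - vy ax| / speed^3` per
#' sample, radius of curvature `R = 1/C` and angular velocity
#' `V = speed * C`. Samples with speed below `speed_epsilon` or curvature
#' below `curvature_epsilon` (or non-finite) are masked and excluded from
#' downstream fits.
#'
#' @param profile a [estimate_derivatives()] result (possibly sliced).
#' @param speed_epsilon,curvature_epsilon numerical floors (cm/s, 1/cm).
#' @return object of class `curvature_profile`: list with vectors `C`, `R`,
#'   `V_ang` and logical `mask` (TRUE = usable sample).
#' @export
curvature_profile <- function(profile, speed_epsilon = 1e-6,
                              curvature_epsilon = 1e-6) {
  sp <- profile$speed
  C <- abs(profile$vx * profile$ay - profile$vy * profile$ax) / pmax(sp, 1e-300)^3
  mask <- is.finite(C) & sp >= speed_epsilon & C >= curvature_epsilon
  if (!any(mask)) stop("degenerate cycle: all samples masked")
  structure(list(C = C, R = 1 / C, V_ang = sp * C, mask = mask),
            class = "curvature_profile")
}

#' Log-log speed-curvature power-law fit
#'
#' Ordinary least squares of `log V` on `log C` (natural logs) over the
#' unmasked samples of one cycle, under the empirical relation
#' `V(t) = K C(t)^(1 - beta)` between angular velocity and curvature. The
#' slope `s` gives `beta = 1 - s`; the velocity gain factor is
#' `K = exp(intercept)`; `corr_coef` is the Pearson r of the same log-log
#' point cloud.
#'
#' @param curv a [curvature_profile()].
#' @param min_points minimum unmasked samples (default 10).
#' @return object of class `power_law_fit`: list with `beta`, `K`,
#'   `corr_coef`, `n_points`.
#' @export
fit_power_law <- function(curv, min_points = 10L) {
  stopifnot(inherits(curv, "curvature_profile"))
  lc <- log(curv$C[curv$mask])
  lv <- log(curv$V_ang[curv$mask])
  if (length(lc) < min_points) {
    stop("power-law fit needs at least ", min_points, " unmasked samples")
  }
  if (diff(range(lc)) < 1e-3) {
    stop("uninformative curvature range: log-curvature spread below 1e-3 ",
         "(near-circular cycle)")
  }
  cf <- stats::lm.fit(cbind(1, lc), lv)$coefficients
  structure(list(beta = 1 - cf[[2]], K = exp(cf[[1]]),
                 corr_coef = stats::cor(lc, lv), n_points = length(lc)),
            class = "power_law_fit")
}

# slice a kinematic profile to a cycle's half-open sample range, keeping the
# boundary sample available for duration/perimeter closure
slice_profile <- function(profile, cycle) {
  n <- length(profile$t)
  idx <- cycle$start:(min(cycle$end, n) - 1L)
  structure(list(t = profile$t[idx], dt = profile$dt,
                 vx = profile$vx[idx], vy = profile$vy[idx],
                 ax = profile$ax[idx], ay = profile$ay[idx],
                 speed = profile$speed[idx]),
            class = "kinematic_profile")
}

#' All per-cycle features (one Table row)
#'
#' Assembles the per-cycle parameter set: duration, peak and mean velocity,
#' the power-law triple (beta, K, corr_coef), and the geometric parameters
#' (eccentricity, semi-axes, aspect ratio, perimeter, relative size,
#' rotation angle).
#'
#' @param traj the parent [trajectory()] (filtered).
#' @param profile its [estimate_derivatives()] result.
#' @param cycle one `cycle_set` row.
#' @param template a [template_spec()] for relative size.
#' @param config an [analysis_config()] supplying the numerical floors.
#' @return a one-row data.frame with column `cycle_index` followed by the
#'   feature columns.
#' @export
analyze_cycle <- function(traj, profile, cycle, template = template_spec(),
                          config = analysis_config()) {
  n <- n_samples(traj)
  i0 <- cycle$start
  i1 <- min(cycle$end, n)
  xy <- as.matrix(traj$samples[i0:i1, c("x", "y")])
  res <- tryCatch({
    fit <- fit_ellipse(xy)
    geo <- geometry_features(fit, xy, template)
    kin <- kinematic_features(cycle, profile)
    pl <- fit_power_law(curvature_profile(slice_profile(profile, cycle),
                                          config$speed_epsilon,
                                          config$curvature_epsilon))
    data.frame(cycle_index = cycle$cycle_index,
               duration = kin$duration, max_v = kin$max_v, mean_v = kin$mean_v,
               beta = pl$beta, K = pl$K, corr_coef = pl$corr_coef,
               eccentricity = geo$eccentricity,
               semi_major = geo$semi_major, semi_minor = geo$semi_minor,
               aspect_ratio = geo$aspect_ratio, perimeter = geo$perimeter,
               relative_size = geo$relative_size,
               rotation_angle = geo$rotation_angle)
  }, error = function(e) {
    stop("cycle ", cycle$cycle_index, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Names of the per-cycle parameters, in report order
#' @export
feature_parameters <- function() {
  c("max_v", "mean_v", "duration", "beta", "K", "corr_coef", "eccentricity",
    "semi_major", "semi_minor", "aspect_ratio", "perimeter", "relative_size")
}
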