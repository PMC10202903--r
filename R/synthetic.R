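#' Generate a harmonic (sinusoidal) elliptical trajectory
#'
#' Harmonic motion `x0(t) = a cos(2 pi f t + phi0)`,
#' `y0(t) = +/- b sin(2 pi f t + phi0)` (sign by tracing direction), rotated
#' and translated. Harmonic tracing of an ellipse is the exact solution of
#' the speed-curvature power law with exponent beta = 1/3, which makes this
#' the canonical noise-free oracle trajectory for the power-law fit.
#'
#' @param a,b semi-major/semi-minor axes (cm), `a >= b > 0`.
#' @param frequency cycle frequency in Hz.
#' @param rotation degrees counterclockwise from the +x axis.
#' @param direction `"CCW"` or `"CW"`.
#' @param phase0 starting phase, radians.
#' @param sample_rate sampling rate in Hz; must exceed `4 * frequency`.
#' @param n_cycles number of full revolutions.
#' @param center ellipse center (cm).
#' @param subject_id,hand,speed trajectory labels.
#' @return a [trajectory()] sampled on `t = 0, 1/rate, ..., n_cycles/frequency`.
#' @examples
#' tr <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1)
#' max(estimate_derivatives(tr)$speed)  # ~ 2*pi*8 = 50.27 cm/s
#' @export
generate_harmonic_cycle <- function(a, b, frequency, rotation = 0,
                                    direction = c("CCW", "CW"), phase0 = 0,
                                    sample_rate = 200, n_cycles = 1,
                                    center = c(0, 0), subject_id = "synthetic",
                                    hand = c("D", "ND"), speed = c("N", "S", "F")) {
  direction <- match.arg(direction)
  if (!(b > 0 && a >= b)) stop("require a >= b > 0")
  if (frequency <= 0) stop("frequency must be positive")
  if (sample_rate < 4 * frequency) {
    stop("aliasing: sample_rate must be at least 4 * frequency")
  }
  tt <- seq(0, n_cycles / frequency, by = 1 / sample_rate)
  th <- 2 * pi * frequency * tt + phase0
  sgn <- if (direction == "CCW") 1 else -1
  xy <- rotate_xy(a * cos(th), sgn * b * sin(th), rotation)
  trajectory(tt, xy$x + center[1], xy$y + center[2],
             subject_id = subject_id, hand = match.arg(hand),
             speed = match.arg(speed), sample_rate = sample_rate)
}

rotate_xy <- function(x, y, rotation_deg) {
  th <- rotation_deg * pi / 180
  list(x = cos(th) * x - sin(th) * y, y = sin(th) * x + cos(th) * y)
}

#' Specification of one power-law ellipse cycle
#'
#' @param a,b semi-axes (cm), `a >= b > 0`.
#' @param beta power-law exponent in (0, 1); 1/3 reproduces harmonic motion.
#' @param duration cycle period in s.
#' @param rotation,center,direction,phase0 as in [generate_harmonic_cycle()].
#' @return list of class `cycle_spec`.
#' @export
cycle_spec <- function(a = 8, b = 2, beta = 1 / 3, duration = 1,
                       rotation = 0, center = c(0, 0),
                       direction = c("CCW", "CW"), phase0 = 0) {
  direction <- match.arg(direction)
  if (!(b > 0 && a >= b)) stop("require a >= b > 0")
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
  if (duration <= 0) stop("duration must be positive")
  structure(list(a = a, b = b, beta = beta, duration = duration,
                 rotation = rotation, center = as.numeric(center),
                 direction = direction, phase0 = phase0),
            class = "cycle_spec")
}

# Time parameterization of one power-law revolution: with ellipse parameter
# phi, |r'(phi)| = sqrt(a^2 sin^2 + b^2 cos^2) and radius of curvature
# R = |r'|^3 / (ab), the tangential speed v = k R^beta gives
# dt/dphi = |r'| / v = |r'|^(1 - 3 beta) (ab)^beta / k. The cumulative
# integral is taken on a fine grid and k is set so one revolution takes
# `duration`. Returns the grid phi and the (scaled) cumulative time.
power_law_time_grid <- function(a, b, beta, duration, phase0, n_grid = 8192) {
  phi <- seq(phase0, phase0 + 2 * pi, length.out = n_grid + 1)
  g <- (sqrt(a^2 * sin(phi)^2 + b^2 * cos(phi)^2))^(1 - 3 * beta) * (a * b)^beta
  tcum <- pracma::cumtrapz(phi, g)[, 1]
  # Richardson step-halving check on the closure integral
  coarse <- pracma::trapz(phi[seq(1, n_grid + 1, by = 2)],
                          g[seq(1, n_grid + 1, by = 2)])
  if (abs(coarse - tcum[n_grid + 1]) > 1e-6 * abs(tcum[n_grid + 1])) {
    stop("resolution error: integration grid too coarse for this cycle")
  }
  list(phi = phi, t = tcum / tcum[n_grid + 1] * duration)
}

#' Generate one ellipse cycle obeying the speed-curvature power law
#'
#' Produces samples whose tangential speed satisfies `v = k * R^beta` along
#' the ellipse (equivalently, angular velocity `V = K * C^(1 - beta)`), with
#' `k` chosen so one revolution takes `spec$duration`. The time course is
#' obtained by integrating `dt/dphi = |r'(phi)| / v(phi)` on a fine
#' parameter grid (8192 steps) and interpolating the inverse map at the
#' uniform sample times. For `beta = 1/3` the output coincides with
#' [generate_harmonic_cycle()].
#'
#' @param spec a [cycle_spec()].
#' @param sample_rate sampling rate in Hz.
#' @param n_grid integration grid resolution (default 8192 steps/cycle).
#' @inheritParams generate_harmonic_cycle
#' @return a [trajectory()] covering exactly one revolution.
#' @export
generate_power_law_cycle <- function(spec, sample_rate = 200, n_grid = 8192,
                                     subject_id = "synthetic",
                                     hand = c("D", "ND"),
                                     speed = c("N", "S", "F")) {
  stopifnot(inherits(spec, "cycle_spec"))
  if (sample_rate * spec$duration < 4) {
    stop("aliasing: fewer than 4 samples per cycle")
  }
  grid <- power_law_time_grid(spec$a, spec$b, spec$beta, spec$duration,
                              spec$phase0, n_grid)
  tt <- seq(0, spec$duration, by = 1 / sample_rate)
  phi <- stats::approx(grid$t, grid$phi, xout = tt, rule = 2)$y
  sgn <- if (spec$direction == "CCW") 1 else -1
  xy <- rotate_xy(spec$a * cos(phi), sgn * spec$b * sin(phi), spec$rotation)
  trajectory(tt, xy$x + spec$center[1], xy$y + spec$center[2],
             subject_id = subject_id, hand = match.arg(hand),
             speed = match.arg(speed), sample_rate = sample_rate)
}

#' Specification of one synthetic recording
#'
#' A recording is `n_cycles` power-law cycles drawn continuously. Per-cycle
#' duration and semi-axes are jittered by multiplicative log-normal factors
#' with coefficient of variation `jitter_cv` (so parameters stay positive),
#' and isotropic Gaussian positional noise of SD `noise_sd` cm is added.
#'
#' @param cycle a [cycle_spec()] giving the nominal cycle.
#' @param n_cycles cycles per recording (default 10, the task's count).
#' @param jitter_cv CV of the per-cycle multiplicative jitter (duration, a, b).
#' @param noise_sd additive positional noise SD in cm.
#' @param sample_rate sampling rate in Hz (default 200, the tablet's rate).
#' @return list of class `recording_spec`.
#' @export
recording_spec <- function(cycle = cycle_spec(), n_cycles = 10,
                           jitter_cv = 0.03, noise_sd = 0.02,
                           sample_rate = 200) {
  stopifnot(inherits(cycle, "cycle_spec"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (jitter_cv < 0) stop("jitter_cv must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(cycle = cycle, n_cycles = as.integer(n_cycles),
                 jitter_cv = jitter_cv, noise_sd = noise_sd,
                 sample_rate = sample_rate),
            class = "recording_spec")
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# multiplicative log-normal factors with mean 1 and coefficient of variation cv
jitter_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a continuous multi-cycle synthetic recording
#'
#' Concatenates `n_cycles` power-law cycles, continuous in position (each
#' jittered cycle is translated so its start coincides with the previous
#' cycle's end point), sampled on a single uniform time grid, with additive
#' Gaussian positional noise. Deterministic given `seed`.
#'
#' @param spec a [recording_spec()].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @inheritParams generate_harmonic_cycle
#' @return a [trajectory()].
#' @export
generate_recording <- function(spec, seed = 1L, subject_id = "synthetic",
                               hand = c("D", "ND"), speed = c("N", "S", "F")) {
  stopifnot(inherits(spec, "recording_spec"))
  hand <- match.arg(hand)
  speed <- match.arg(speed)
  with_seed(seed, {
    nc <- spec$n_cycles
    base <- spec$cycle
    fd <- jitter_factors(nc, spec$jitter_cv)
    fa <- jitter_factors(nc, spec$jitter_cv)
    fb <- jitter_factors(nc, spec$jitter_cv)
    grids <- vector("list", nc)
    pars <- vector("list", nc)
    t_end <- numeric(nc)
    for (k in seq_len(nc)) {
      pars[[k]] <- list(a = base$a * fa[k], b = base$b * fb[k],
                        duration = base$duration * fd[k])
      grids[[k]] <- power_law_time_grid(pars[[k]]$a, pars[[k]]$b, base$beta,
                                        pars[[k]]$duration, base$phase0)
      t_end[k] <- pars[[k]]$duration
    }
    t_off <- cumsum(c(0, t_end))[seq_len(nc)]
    total <- sum(t_end)
    sgn <- if (base$direction == "CCW") 1 else -1
    pos_at <- function(k, phi) {
      xy <- rotate_xy(pars[[k]]$a * cos(phi), sgn * pars[[k]]$b * sin(phi),
                      base$rotation)
      cbind(xy$x, xy$y)
    }
    # positional offsets making the concatenation continuous
    off <- matrix(0, nc, 2)
    for (k in seq_len(nc)[-1]) {
      end_prev <- pos_at(k - 1, base$phase0 + 2 * pi) + off[k - 1, ]
      off[k, ] <- end_prev - pos_at(k, base$phase0)
    }
    tt <- seq(0, total, by = 1 / spec$sample_rate)
    cyc_idx <- pmin(findInterval(tt, t_off), nc)
    x <- numeric(length(tt))
    y <- numeric(length(tt))
    for (k in seq_len(nc)) {
      sel <- cyc_idx == k
      phi <- stats::approx(grids[[k]]$t, grids[[k]]$phi,
                           xout = tt[sel] - t_off[k], rule = 2)$y
      p <- pos_at(k, phi)
      x[sel] <- p[, 1] + off[k, 1] + base$center[1]
      y[sel] <- p[, 2] + off[k, 2] + base$center[2]
    }
    if (spec$noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, spec$noise_sd)
      y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
    }
    trajectory(tt, x, y, subject_id = subject_id, hand = hand, speed = speed,
               sample_rate = spec$sample_rate)
  })
}

#' Specification of a synthetic cohort
#'
#' Emulates the study design: `n_subjects` subjects, each recorded with both
#' hands at three speeds (slow, normal, fast), 10 continuously drawn
#' ellipses per recording. Subject-level movement duration and size (vigor)
#' are idiosyncratic log-normal draws shared across hands through a latent
#' factor with correlation `cross_hand_correlation`; the non-dominant hand
#' draws slightly more circular ellipses (`nd_eccentricity_shift` added to
#' the aspect ratio b/a) and traces clockwise, the dominant hand
#' counterclockwise.
#'
#' Defaults reflect the study conditions: normal-pace median cycle duration
#' 1.67 s with speed multipliers 2.2 (slow) and 0.63 (fast), subject log-SD
#' 0.35, power-law exponent beta ~ N(1/3, 0.01), cross-hand correlation 0.9.
#'
#' @param n_subjects number of subjects (default 40).
#' @param speed_duration_multipliers named factors for `S`, `N`, `F`.
#' @param nd_eccentricity_shift additive change of aspect ratio b/a for the
#'   non-dominant hand (toward circularity).
#' @param subject_duration_dist `c(median, log_sd)` of the log-normal
#'   subject-level normal-pace cycle duration (s).
#' @param subject_beta_dist `c(mean, sd)` of the subject-level exponent.
#' @param subject_size_log_sd log-SD of the subject-level size (vigor) factor.
#' @param cross_hand_correlation target correlation of subject-level
#'   duration/size/beta across hands, in \[0, 1\].
#' @param recording a [recording_spec()] providing jitter, noise, cycle
#'   count and sampling defaults.
#' @param seed integer base seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40,
                        speed_duration_multipliers = c(S = 2.2, N = 1.0, F = 0.63),
                        nd_eccentricity_shift = 0.015,
                        subject_duration_dist = c(median = 1.67, log_sd = 0.35),
                        subject_beta_dist = c(mean = 1 / 3, sd = 0.01),
                        subject_size_log_sd = 0.05,
                        cross_hand_correlation = 0.9,
                        recording = recording_spec(), seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (any(speed_duration_multipliers <= 0)) stop("speed multipliers must be > 0")
  if (!all(c("S", "N", "F") %in% names(speed_duration_multipliers))) {
    stop("speed_duration_multipliers must name S, N and F")
  }
  if (cross_hand_correlation < 0 || cross_hand_correlation > 1) {
    stop("cross_hand_correlation must lie in [0, 1]")
  }
  stopifnot(inherits(recording, "recording_spec"))
  structure(list(
    n_subjects = as.integer(n_subjects),
    speed_duration_multipliers = speed_duration_multipliers,
    nd_eccentricity_shift = nd_eccentricity_shift,
    subject_duration_dist = subject_duration_dist,
    subject_beta_dist = subject_beta_dist,
    subject_size_log_sd = subject_size_log_sd,
    cross_hand_correlation = cross_hand_correlation,
    recording = recording, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Draw the subject- and recording-level generating parameters of a cohort
#'
#' The stochastic core of [generate_cohort()], exposed separately so the
#' statistical structure (cross-hand correlation, subject idiosyncrasy) can
#' be studied without synthesizing trajectories. Hand sharing uses a shared
#' latent factor: `z_hand = sqrt(rho) z_subject + sqrt(1 - rho) e_hand`,
#' giving correlation `rho` between the two hands' parameters.
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with one row per recording (subject x hand x speed)
#'   and columns `subject`, `hand`, `speed`, `duration`, `beta`, `a`, `b`,
#'   `rotation`, `direction`, `rec_seed`.
#' @export
draw_cohort_parameters <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_subjects
    rho <- spec$cross_hand_correlation
    latent_pair <- function() {
      z <- stats::rnorm(ns)
      cbind(D = sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(ns),
            ND = sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(ns))
    }
    z_dur <- latent_pair()
    z_size <- latent_pair()
    z_beta <- latent_pair()
    dd <- spec$subject_duration_dist
    bd <- spec$subject_beta_dist
    dur_hand <- dd[[1]] * exp(dd[[2]] * z_dur)              # ns x 2
    size_hand <- exp(spec$subject_size_log_sd * z_size)     # ns x 2
    beta_hand <- pmin(pmax(bd[[1]] + bd[[2]] * z_beta, 0.05), 0.95)
    base <- spec$recording$cycle
    rows <- expand.grid(speed = c("S", "N", "F"), hand = c("D", "ND"),
                        subject = sprintf("S%02d", seq_len(ns)),
                        stringsAsFactors = FALSE)[, 3:1]
    hi <- ifelse(rows$hand == "D", 1L, 2L)
    si <- match(rows$subject, sprintf("S%02d", seq_len(ns)))
    a <- base$a * size_hand[cbind(si, hi)]
    ar <- base$b / base$a + ifelse(rows$hand == "ND", spec$nd_eccentricity_shift, 0)
    data.frame(
      rows,
      duration = dur_hand[cbind(si, hi)] *
        spec$speed_duration_multipliers[rows$speed],
      beta = beta_hand[cbind(si, hi)],
      a = a,
      b = a * ar,
      rotation = ifelse(rows$hand == "D", base$rotation + 45, base$rotation - 45),
      direction = ifelse(rows$hand == "D", "CCW", "CW"),
      rec_seed = (spec$seed + seq_len(nrow(rows)) * 7919L) %% .Machine$integer.max,
      row.names = NULL
    )
  })
}

#' Generate a full synthetic cohort of drawing recordings
#'
#' Synthesizes one [trajectory()] per subject x hand x speed from the
#' parameters drawn by [draw_cohort_parameters()], and returns both the
#' recordings and the ground-truth table for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `trajectories` (list of [trajectory()],
#'   named `subject_hand_speed`) and `truth` (the parameter data.frame).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- draw_cohort_parameters(spec)
  rec <- spec$recording
  trajs <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    p <- truth[i, ]
    cs <- cycle_spec(a = p$a, b = p$b, beta = p$beta, duration = p$duration,
                     rotation = p$rotation, center = rec$cycle$center,
                     direction = p$direction, phase0 = rec$cycle$phase0)
    rs <- recording_spec(cycle = cs, n_cycles = rec$n_cycles,
                         jitter_cv = rec$jitter_cv, noise_sd = rec$noise_sd,
                         sample_rate = rec$sample_rate)
    trajs[[i]] <- generate_recording(rs, seed = p$rec_seed,
                                     subject_id = p$subject, hand = p$hand,
                                     speed = p$speed)
  }
  names(trajs) <- paste(truth$subject, truth$hand, truth$speed, sep = "_")
  list(trajectories = trajs, truth = truth)
}
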