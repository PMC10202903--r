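test_that("harmonic cycle matches closed-form kinematics", {
  tr <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1)
  prof <- estimate_derivatives(tr)
  # peak tangential speed 2*pi*f*a
  expect_equal(max(prof$speed), 2 * pi * 8, tolerance = 0.1 / (2 * pi * 8))
  # circle: constant speed 2*pi, constant curvature 1
  circ <- generate_harmonic_cycle(a = 1, b = 1, frequency = 1)
  pc <- estimate_derivatives(circ)
  expect_lt(max(abs(pc$speed - 2 * pi)), 0.01)
  cp <- curvature_profile(pc)
  expect_lt(max(abs(cp$C[10:190] - 1)), 1e-3)
  # fitted eccentricity of the template-sized ellipse
  fit <- fit_ellipse(tr$samples$x, tr$samples$y)
  expect_equal(eccentricity_from_axes(fit$a, fit$b), 0.968, tolerance = 5e-4)
  # aliasing guard
  expect_error(generate_harmonic_cycle(a = 2, b = 1, frequency = 10,
                                       sample_rate = 30), "aliasing")
})

test_that("power-law generator reduces to harmonic motion at beta = 1/3", {
  h <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1)
  p <- generate_power_law_cycle(cycle_spec(a = 8, b = 2, beta = 1 / 3,
                                           duration = 1))
  d <- sqrt((h$samples$x - p$samples$x)^2 + (h$samples$y - p$samples$y)^2)
  expect_lt(max(d), 1e-4)
})

test_that("power-law generator on a circle gives constant speed for any beta", {
  for (b in c(0.2, 0.5, 0.8)) {
    tr <- generate_power_law_cycle(cycle_spec(a = 3, b = 3, beta = b,
                                              duration = 1))
    sp <- estimate_derivatives(tr)$speed
    expect_lt(diff(range(sp[5:196])), 1e-6)
  }
})

test_that("noise-free cycles close on themselves", {
  for (b in c(0.25, 1 / 3, 0.45)) {
    tr <- generate_power_law_cycle(cycle_spec(a = 8, b = 2, beta = b,
                                              duration = 1))
    s <- tr$samples
    n <- nrow(s)
    expect_lt(sqrt((s$x[n] - s$x[1])^2 + (s$y[n] - s$y[1])^2), 1e-4)
  }
})

test_that("generator-fitter round trip recovers beta across the grid", {
  for (b in c(0.25, 0.30, 1 / 3, 0.40, 0.45)) {
    for (dir in c("CCW", "CW")) {
      tr <- generate_power_law_cycle(cycle_spec(a = 8, b = 2, beta = b,
                                                duration = 1, direction = dir))
      pl <- fit_power_law(curvature_profile(estimate_derivatives(tr)))
      expect_lt(abs(pl$beta - b), 0.005)
    }
  }
})

test_that("recordings are deterministic given the seed and jitter-free when asked", {
  rs <- recording_spec(cycle = cycle_spec(duration = 1), n_cycles = 10,
                       jitter_cv = 0.03, noise_sd = 0.02)
  a <- generate_recording(rs, seed = 7)
  b <- generate_recording(rs, seed = 7)
  expect_identical(a$samples, b$samples)
  c <- generate_recording(rs, seed = 8)
  expect_false(identical(a$samples, c$samples))
  # the private stream leaves the caller's RNG untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_recording(rs, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)

  quiet <- recording_spec(cycle = cycle_spec(duration = 1), n_cycles = 10,
                          jitter_cv = 0, noise_sd = 0)
  tr <- generate_recording(quiet, seed = 1)
  cycles <- exclude_cycles(segment_cycles(tr))
  prof <- estimate_derivatives(tr)
  durs <- vapply(seq_len(nrow(cycles)), function(i)
    kinematic_features(cycles[i, ], prof)$duration, 0)
  expect_lt(coefficient_of_variation(durs), 1e-9)
  expect_identical(nrow(segment_cycles(tr)), 10L)
})

test_that("per-cycle duration jitter propagates to the measured CV", {
  rs <- recording_spec(cycle = cycle_spec(duration = 1), n_cycles = 10,
                       jitter_cv = 0.05, noise_sd = 0)
  cvs <- vapply(1:20, function(s) {
    tr <- generate_recording(rs, seed = s)
    cycles <- segment_cycles(tr)   # all 10 cycles: better CV estimate
    prof <- estimate_derivatives(tr)
    durs <- vapply(seq_len(nrow(cycles)), function(i)
      kinematic_features(cycles[i, ], prof)$duration, 0)
    coefficient_of_variation(durs)
  }, 0)
  # CV of a CV estimate from 10 log-normal draws is ~24%; 20 replicates
  # bring the mean within a few percent of the target
  expect_equal(mean(cvs), 0.05, tolerance = 0.15)
})

test_that("cohort layout, hand assignment and tracing direction follow the design", {
  spec <- cohort_spec(n_subjects = 40, seed = 3)
  truth <- draw_cohort_parameters(spec)
  expect_identical(nrow(truth), 240L)
  expect_identical(as.integer(table(truth$hand)), c(120L, 120L))
  expect_true(all(truth$direction[truth$hand == "D"] == "CCW"))
  expect_true(all(truth$direction[truth$hand == "ND"] == "CW"))
  expect_true(all(truth$rotation[truth$hand == "D"] == 45))
  expect_true(all(truth$rotation[truth$hand == "ND"] == -45))
  # ND draws are more circular by the configured aspect-ratio shift
  ar_d <- with(truth[truth$hand == "D", ], b / a)
  ar_nd <- with(truth[truth$hand == "ND", ], b / a)
  expect_equal(mean(ar_nd) - mean(ar_d), 0.015, tolerance = 1e-9)
  # slow > normal > fast durations within every subject/hand
  wide <- reshape(truth[, c("subject", "hand", "speed", "duration")],
                  idvar = c("subject", "hand"), timevar = "speed",
                  direction = "wide")
  expect_true(all(wide$duration.S > wide$duration.N))
  expect_true(all(wide$duration.N > wide$duration.F))
})

test_that("perfect cross-hand sharing yields identical subject parameters", {
  spec <- cohort_spec(n_subjects = 10, cross_hand_correlation = 1, seed = 5)
  truth <- draw_cohort_parameters(spec)
  n <- truth[truth$speed == "N", ]
  d <- n[n$hand == "D", ]
  nd <- n[n$hand == "ND", ]
  expect_equal(d$duration[match(nd$subject, d$subject)], nd$duration,
               tolerance = 1e-12)
})

test_that("cross-hand correlation of drawn parameters tracks the target", {
  rs <- vapply(1:50, function(s) {
    truth <- draw_cohort_parameters(cohort_spec(n_subjects = 40,
                                                cross_hand_correlation = 0.9,
                                                seed = s))
    n <- truth[truth$speed == "N", ]
    d <- n[n$hand == "D", ]
    nd <- n[n$hand == "ND", ]
    cor(log(d$duration[match(nd$subject, d$subject)]), log(nd$duration))
  }, 0)
  est <- tanh(mean(atanh(rs)))
  ci <- tanh(atanh(0.9) + c(-1, 1) * 1.96 / sqrt(40 - 3))
  expect_gt(est, ci[1])
  expect_lt(est, ci[2])
  # and a null cohort stays near zero
  rs0 <- vapply(1:50, function(s) {
    truth <- draw_cohort_parameters(cohort_spec(n_subjects = 40,
                                                cross_hand_correlation = 0,
                                                seed = 100 + s))
    n <- truth[truth$speed == "N", ]
    d <- n[n$hand == "D", ]
    nd <- n[n$hand == "ND", ]
    cor(log(d$duration[match(nd$subject, d$subject)]), log(nd$duration))
  }, 0)
  expect_lt(abs(mean(rs0)), 2 / sqrt(40 * 50 / (1 + 49 * 0)))
})

test_that("generated cohorts produce one trajectory per condition", {
  spec <- cohort_spec(n_subjects = 2, seed = 9,
                      recording = recording_spec(
                        cycle = cycle_spec(duration = 1), n_cycles = 3))
  cohort <- generate_cohort(spec)
  expect_length(cohort$trajectories, 12L)
  expect_identical(names(cohort$trajectories)[1], "S01_D_S")
  for (tr in cohort$trajectories) expect_silent(validate_trajectory(tr))
})
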