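test_that("the direct least-squares fit recovers exact ellipses", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  for (rot in c(-60, 0, 45, 80)) {
    xy <- with(list(c = cos(rot * pi / 180), s = sin(rot * pi / 180)),
               cbind(c * 8 * cos(th) - s * 2 * sin(th) + 3,
                     s * 8 * cos(th) + c * 2 * sin(th) - 1))
    fit <- fit_ellipse(xy)
    expect_equal(fit$a, 8, tolerance = 1e-6)
    expect_equal(fit$b, 2, tolerance = 1e-6)
    expect_equal(fit$orientation, rot, tolerance = 1e-6)
    expect_equal(fit$center, c(3, -1), tolerance = 1e-6)
    expect_lt(fit$rms_residual, 1e-9)
  }
})

test_that("degenerate inputs are rejected and circles get orientation 0", {
  expect_error(fit_ellipse(cbind(1:20, 2 * (1:20))), "collinear|ellipse")
  expect_error(fit_ellipse(cbind(1:5, c(2, 1, 3, 2, 4))), "at least 6 points")
  th <- seq(0, 2 * pi, length.out = 50)
  fit <- fit_ellipse(cbind(3 * cos(th), 3 * sin(th)))
  expect_equal(fit$a, fit$b, tolerance = 1e-9)
  expect_identical(fit$orientation, 0)
})

test_that("eccentricity, aspect ratio and perimeter follow their definitions", {
  expect_equal(round(eccentricity_from_axes(8, 2), 3), 0.968)
  expect_equal(eccentricity_from_axes(3, 3), 0)
  # e = sqrt(1 - ar^2) identity on a grid of shapes
  for (ar in seq(0.1, 1, by = 0.1)) {
    expect_equal(eccentricity_from_axes(5, 5 * ar), sqrt(1 - ar^2),
                 tolerance = 1e-9)
  }
  # elliptic-integral perimeter against independent quadrature
  for (ab in list(c(8, 2), c(5, 4), c(3, 3))) {
    expect_equal(ellipse_perimeter(ab[1], ab[2]),
                 ellipse_perimeter_quadrature(ab[1], ab[2]),
                 tolerance = 1e-8)
  }
  expect_equal(ellipse_perimeter(8, 2), 34.3136, tolerance = 1e-4)
})

test_that("geometry features of a noise-free template cycle are faithful", {
  tr <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1, rotation = 45)
  xy <- as.matrix(tr$samples[, c("x", "y")])
  fit <- fit_ellipse(xy)
  geo <- geometry_features(fit, xy, template_spec())
  expect_equal(geo$eccentricity, 0.968, tolerance = 5e-4)
  expect_equal(geo$rotation_angle, 45, tolerance = 0.1)
  expect_equal(geo$aspect_ratio, 0.25, tolerance = 1e-3)
  expect_equal(geo$relative_size, 1, tolerance = 2e-3)
})

test_that("derivative-based curvature matches closed forms and the Menger oracle", {
  circ <- generate_harmonic_cycle(a = 2, b = 2, frequency = 1)
  cp <- curvature_profile(estimate_derivatives(circ))
  expect_lt(max(abs(cp$C[10:190] - 0.5)), 1e-3)
  expect_lt(max(abs(cp$R * cp$C - 1)), 1e-9)

  ell <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1)
  cp <- curvature_profile(estimate_derivatives(ell))
  # vertices: t = 0.5 is a major-axis vertex (phase pi), t = 0.25 minor
  i_major <- 101; i_minor <- 51
  expect_equal(cp$C[i_major], 8 / 4, tolerance = 0.01 * 2)
  expect_equal(cp$C[i_minor], 2 / 64, tolerance = 0.01 * 2 / 64)
  # against the independent three-point (Menger) estimator
  # both estimators converge at O(h^2) with different constants
  mg <- menger_curvature(ell$samples$x, ell$samples$y)
  expect_equal(cp$C[mg$index], mg$C, tolerance = 5e-3)
})

test_that("the log-log fit recovers the 1/3 law on harmonic ellipses", {
  tr <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1)
  pl <- fit_power_law(curvature_profile(estimate_derivatives(tr)))
  expect_equal(pl$beta, 0.333, tolerance = 0.003 / 0.333)
  expect_gt(pl$corr_coef, 0.999)
  # velocity gain factor: V = 2 pi f (ab)^(1/3) C^(2/3)
  expect_equal(pl$K, 2 * pi * 16^(1 / 3), tolerance = 0.01)
  # a constant-speed circle has no curvature range to regress on
  circ <- generate_harmonic_cycle(a = 2, b = 2, frequency = 1)
  expect_error(fit_power_law(curvature_profile(estimate_derivatives(circ))),
               "uninformative curvature range")
})

test_that("analyze_cycle assembles consistent per-cycle records", {
  rs <- recording_spec(cycle = cycle_spec(duration = 1), n_cycles = 10,
                       jitter_cv = 0, noise_sd = 0)
  tr <- generate_recording(rs, seed = 1)
  res <- analyze_recording(tr)
  feats <- res$features
  expect_identical(nrow(feats), 7L)
  # jitter-free recording: identical features across retained cycles
  for (p in feature_parameters()) {
    expect_lt(diff(range(feats[[p]])) / max(abs(mean(feats[[p]])), 1e-12),
              1e-6)
  }
  expect_equal(feats$aspect_ratio, feats$semi_minor / feats$semi_major,
               tolerance = 1e-9)
  expect_equal(feats$eccentricity, sqrt(1 - feats$aspect_ratio^2),
               tolerance = 1e-9)
  expect_true(all(feats$max_v >= feats$mean_v))
})

test_that("features are chirality-invariant", {
  cfg <- analysis_config()
  f_of <- function(dir, rot) {
    tr <- generate_harmonic_cycle(a = 8, b = 2, frequency = 1, n_cycles = 4,
                                  rotation = rot, direction = dir,
                                  hand = if (dir == "CW") "ND" else "D")
    prof <- estimate_derivatives(tr)
    cyc <- segment_cycles(tr)[2, ]
    analyze_cycle(tr, prof, cyc, template_spec(), cfg)
  }
  ccw <- f_of("CCW", 30)
  cw <- f_of("CW", 30)   # mirrored twin
  for (p in c("duration", "max_v", "mean_v", "beta", "K", "eccentricity",
              "perimeter")) {
    expect_equal(ccw[[p]], cw[[p]], tolerance = 1e-6,
                 label = paste("parameter", p))
  }
})

test_that("eccentricity of fitted generator output matches the generating shape", {
  for (ar in c(0.25, 0.5, 0.8)) {
    tr <- generate_power_law_cycle(cycle_spec(a = 6, b = 6 * ar,
                                              beta = 1 / 3, duration = 1))
    fit <- fit_ellipse(as.matrix(tr$samples[, c("x", "y")]))
    expect_equal(eccentricity_from_axes(fit$a, fit$b), sqrt(1 - ar^2),
                 tolerance = 1e-3)
  }
})
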