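#' Direct least-squares ellipse fit
#'
#' Fits the conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` constrained to
#' an ellipse (`4AC - B^2 = 1`) by the numerically stable partitioned
#' eigen-solution of the direct least-squares problem, then converts the
#' conic to center, semi-axes and orientation. The data are centered before
#' fitting for conditioning.
#'
#' @param x,y sample coordinates (cm); `y` may be omitted if `x` is a
#'   two-column matrix or data.frame.
#' @return an object of class `ellipse_fit`: list with `center` (cm),
#'   `a`, `b` (semi-major/minor, cm), `orientation` (degrees in (-90, 90];
#'   0 by convention for a circle), and `rms_residual` (cm, Sampson
#'   distance).
#' @export
fit_ellipse <- function(x, y = NULL) {
  if (is.null(y)) {
    xy <- as.matrix(x)
    x <- xy[, 1]; y <- xy[, 2]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 6L) stop("ellipse fit needs at least 6 points")
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  if (max(abs(xc)) < 1e-12 && max(abs(yc)) < 1e-12) stop("degenerate points")
  D1 <- cbind(xc^2, xc * yc, yc^2)
  D2 <- cbind(xc, yc, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("degenerate (collinear?) points: ", conditionMessage(e))
  })
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stop("fit did not yield an ellipse")
  a1 <- Re(ev$vectors[, ok[1]])
  coefs <- c(a1, as.vector(T1 %*% a1))          # A B C D E F (centered frame)
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; FF <- coefs[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("fit did not yield an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + FF
  Mq <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Mq, symmetric = TRUE)
  ax2 <- -F0 / eq$values                        # squared semi-axes
  if (any(ax2 <= 0)) stop("fit did not yield an ellipse")
  semi <- sqrt(ax2)                             # eigen: decreasing values -> increasing axes
  major_i <- which.max(semi)
  a_fit <- semi[major_i]
  b_fit <- min(semi)
  v <- eq$vectors[, major_i]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90               # to (-90, 90]
  if (ang <= -90) ang <- ang + 180
  if ((a_fit - b_fit) / a_fit < 1e-8) ang <- 0  # circle convention
  # Sampson (gradient-weighted algebraic) residual
  Q <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + FF
  gx <- 2 * A * xc + B * yc + D
  gy <- B * xc + 2 * C * yc + E
  samp <- abs(Q) / pmax(sqrt(gx^2 + gy^2), 1e-12)
  structure(list(center = c(x0 + mx, y0 + my), a = a_fit, b = b_fit,
                 orientation = ang, rms_residual = sqrt(mean(samp^2))),
            class = "ellipse_fit")
}

#' Perimeter of an ellipse by complete elliptic integral
#'
#' `P = 4 a E(m)` with `m = 1 - (b/a)^2`, accurate to better than 1e-8
#' relative.
#'
#' @param a,b semi-axes, `a >= b > 0`.
#' @return perimeter in the units of `a`.
#' @export
ellipse_perimeter <- function(a, b) {
  if (!(b > 0 && a >= b)) stop("require a >= b > 0")
  4 * a * pracma::ellipke(1 - (b / a)^2)$e
}

#' Eccentricity from semi-axes
#'
#' `e = sqrt(1 - (b/a)^2)`: 0 for a circle, approaching 1 for an elongated
#' ellipse. The 8 x 2 cm template has e = 0.968.
#'
#' @param a,b semi-major and semi-minor axes.
#' @export
eccentricity_from_axes <- function(a, b) {
  if (!(b > 0 && a >= b)) stop("require a >= b > 0")
  sqrt(1 - (b / a)^2)
}

#' Geometric features of one drawn cycle
#'
#' Eccentricity, semi-axes, aspect ratio and orientation come from the
#' fitted ellipse; the perimeter is the polyline arc length of the cycle's
#' samples (closed over the cycle boundary); relative size is that
#' perimeter divided by the template perimeter (elliptic integral).
#'
#' @param fit an [fit_ellipse()] result for the cycle.
#' @param xy two-column matrix of the cycle's samples, ordered, covering one
#'   revolution; the first point of the next revolution may be appended by
#'   the caller to close the path.
#' @param template a [template_spec()].
#' @return list with `eccentricity`, `semi_major`, `semi_minor`,
#'   `aspect_ratio`, `perimeter`, `relative_size`, `rotation_angle`.
#' @export
geometry_features <- function(fit, xy, template = template_spec()) {
  stopifnot(inherits(fit, "ellipse_fit"))
  xy <- as.matrix(xy)
  per <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  list(
    eccentricity = eccentricity_from_axes(fit$a, fit$b),
    semi_major = fit$a,
    semi_minor = fit$b,
    aspect_ratio = fit$b / fit$a,
    perimeter = per,
    relative_size = per / ellipse_perimeter(template$a, template$b),
    rotation_angle = fit$orientation
  )
}
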