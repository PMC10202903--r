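#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' intra-trial variability index computed over the retained cycles of one
#' recording.
#'
#' @param values numeric vector, at least 2 values with positive mean.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("CV needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("CV undefined: mean must be positive")
  stats::sd(values) / m
}

#' Per-recording condition summary
#'
#' Mean, SD and CV of each per-cycle parameter over the retained cycles of
#' one recording (one subject x hand x speed cell).
#'
#' @param features the per-cycle feature table of one recording (from
#'   [analyze_recording()] or row-bound [analyze_cycle()] output).
#' @param subject_id,hand,speed condition labels.
#' @param parameters which feature columns to summarize.
#' @return a long data.frame with columns `subject`, `hand`, `speed`,
#'   `parameter`, `mean`, `sd`, `cv`, `n_cycles`.
#' @export
summarize_condition <- function(features, subject_id = "anon", hand = "D",
                                speed = "N", parameters = feature_parameters()) {
  if (nrow(features) < 2L) stop("need at least 2 retained cycles to summarize")
  missing_p <- setdiff(parameters, names(features))
  if (length(missing_p)) stop("missing feature column(s): ",
                              paste(missing_p, collapse = ", "))
  m <- vapply(parameters, function(p) mean(features[[p]]), 0)
  s <- vapply(parameters, function(p) stats::sd(features[[p]]), 0)
  data.frame(subject = subject_id, hand = hand, speed = speed,
             parameter = parameters, mean = m, sd = s, cv = s / m,
             n_cycles = nrow(features), row.names = NULL)
}

# subject-aligned D and ND vectors for one parameter/speed/statistic
cross_hand_vectors <- function(summaries, parameter, speed,
                               statistic = c("mean", "cv")) {
  statistic <- match.arg(statistic)
  sub <- summaries[summaries$parameter == parameter & summaries$speed == speed, ]
  d <- sub[sub$hand == "D", ]
  nd <- sub[sub$hand == "ND", ]
  common <- intersect(d$subject, nd$subject)
  if (length(common) < 3L) stop("need at least 3 subjects with both hands")
  list(D = d[[statistic]][match(common, d$subject)],
       ND = nd[[statistic]][match(common, nd$subject)],
       subjects = common)
}

#' Cross-hand accuracy correlation
#'
#' Pearson correlation, across subjects, between the dominant- and
#' non-dominant-hand per-recording means of one parameter at one speed: the
#' degree to which the ND hand reproduces the D hand's average response.
#'
#' @param summaries row-bound [summarize_condition()] tables for a cohort.
#' @param parameter parameter name (see [feature_parameters()]).
#' @param speed `"S"`, `"N"` or `"F"`.
#' @return list with `r`, `p` (two-sided, t transform), `n`.
#' @export
correlation_accuracy <- function(summaries, parameter, speed) {
  v <- cross_hand_vectors(summaries, parameter, speed, "mean")
  pearson_correlation(v$D, v$ND)
}

#' Cross-hand precision correlation
#'
#' As [correlation_accuracy()] but on the per-subject coefficients of
#' variation: whether a subject's intra-trial variability on the D hand
#' predicts their variability on the ND hand.
#'
#' @inheritParams correlation_accuracy
#' @export
correlation_precision <- function(summaries, parameter, speed) {
  v <- cross_hand_vectors(summaries, parameter, speed, "cv")
  pearson_correlation(v$D, v$ND)
}

pearson_correlation <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in one vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Steiger test for two dependent correlations
#'
#' Z-test for the difference between two dependent Pearson correlations
#' (Steiger 1980): both correlations are Fisher-z transformed and their
#' covariance is estimated from the cross-correlations of the underlying
#' variables, with the pooled correlation substituted in the covariance
#' term. The default, non-overlapping variant compares r(a, b) with
#' r(c, d) for four distinct variables measured on the same subjects (e.g.
#' the D-ND correlation of a parameter at two speeds); the overlapping
#' variant compares r(a, b) with r(a, c), which share variable `a`.
#'
#' @param r_ab,r_cd the two correlations under comparison. For the
#'   overlapping variant, `r_cd` is r(a, c).
#' @param n number of subjects (>= 4).
#' @param cross for `"nonoverlapping"`, the four cross-correlations as a
#'   named or positional vector `(r_ac, r_ad, r_bc, r_bd)`; for
#'   `"overlapping"`, the single correlation r(b, c).
#' @param variant `"nonoverlapping"` (default) or `"overlapping"`.
#' @return list with `Z` and two-sided `p`.
#' @examples
#' steiger_test(0.8, 0.3, n = 40, cross = c(0, 0, 0, 0))$Z  # 3.394
#' @export
steiger_test <- function(r_ab, r_cd, n, cross,
                         variant = c("nonoverlapping", "overlapping")) {
  variant <- match.arg(variant)
  if (n < 4L) stop("Steiger test needs n >= 4")
  rr <- c(r_ab, r_cd, cross)
  if (any(!is.finite(rr)) || any(abs(rr) > 1)) {
    stop("correlations must lie in [-1, 1]")
  }
  rbar <- (r_ab + r_cd) / 2
  if (variant == "nonoverlapping") {
    if (length(cross) != 4L) {
      stop("nonoverlapping variant needs cross = (r_ac, r_ad, r_bc, r_bd)")
    }
    r_ac <- cross[[1]]; r_ad <- cross[[2]]; r_bc <- cross[[3]]; r_bd <- cross[[4]]
    Rm <- matrix(c(1, r_ab, r_ac, r_ad,
                   r_ab, 1, r_bc, r_bd,
                   r_ac, r_bc, 1, r_cd,
                   r_ad, r_bd, r_cd, 1), 4, 4)
    if (min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("correlation matrix is not positive semi-definite")
    }
    # Dunn & Clark covariance with pooled rbar (Steiger's modification)
    psi <- 0.5 * rbar^2 * (r_ac^2 + r_ad^2 + r_bc^2 + r_bd^2) +
      r_ac * r_bd + r_ad * r_bc -
      (rbar * r_ac * r_ad + rbar * r_bc * r_bd +
         rbar * r_ac * r_bc + rbar * r_ad * r_bd)
    cz <- psi / (1 - rbar^2)^2
  } else {
    if (length(cross) != 1L) stop("overlapping variant needs cross = r_bc")
    r_bc <- cross[[1]]
    Rm <- matrix(c(1, r_ab, r_cd,
                   r_ab, 1, r_bc,
                   r_cd, r_bc, 1), 3, 3)
    if (min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("correlation matrix is not positive semi-definite")
    }
    cz <- (r_bc * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_bc^2)) /
      (1 - rbar^2)^2
  }
  Z <- (atanh(r_ab) - atanh(r_cd)) * sqrt((n - 3) / (2 - 2 * cz))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}
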