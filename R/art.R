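#' Aligned Rank Transform for a two-factor within-subject design
#'
#' For each effect of the hand x speed factorial (two main effects and the
#' interaction), the response is aligned by removing every cell-mean
#' estimate except the effect of interest, then midranked over all
#' observations. With cell means `m_hs`, marginal means `m_h`, `m_s` and
#' grand mean `g`:
#' hand alignment `y - m_hs + (m_h - g)`, speed alignment
#' `y - m_hs + (m_s - g)`, interaction alignment `y - m_h - m_s + g`.
#'
#' @param data data.frame with the response and factor columns.
#' @param response,hand,speed column names.
#' @return `data` with six added columns `aligned_hand`, `aligned_speed`,
#'   `aligned_interaction` and their midrank counterparts `rank_*`.
#' @export
align_rank_transform <- function(data, response = "value", hand = "hand",
                                 speed = "speed") {
  for (col in c(response, hand, speed)) {
    if (!col %in% names(data)) stop("missing column: ", col)
  }
  fh <- factor(data[[hand]])
  fs <- factor(data[[speed]])
  if (nlevels(fh) < 2L) stop("factor '", hand, "' needs at least 2 levels")
  if (nlevels(fs) < 2L) stop("factor '", speed, "' needs at least 2 levels")
  y <- data[[response]]
  g <- mean(y)
  m_h <- stats::ave(y, fh)
  m_s <- stats::ave(y, fs)
  m_hs <- stats::ave(y, fh, fs)
  data$aligned_hand <- y - m_hs + (m_h - g)
  data$aligned_speed <- y - m_hs + (m_s - g)
  data$aligned_interaction <- y - m_h - m_s + g
  for (eff in c("hand", "speed", "interaction")) {
    data[[paste0("rank_", eff)]] <- rank(data[[paste0("aligned_", eff)]],
                                         ties.method = "average")
  }
  data
}

# closed-form balanced factorial sums of squares with an additive subject
# block; valid because complete crossing makes the factors orthogonal
balanced_anova_ss <- function(r, fh, fs, fsub) {
  g <- mean(r)
  ss <- function(f) {
    m <- tapply(r, f, mean)
    n <- tapply(r, f, length)
    sum(n * (m - g)^2)
  }
  cell <- interaction(fh, fs)
  ss_h <- ss(fh); ss_s <- ss(fs); ss_cell <- ss(cell); ss_sub <- ss(fsub)
  list(hand = ss_h, speed = ss_s, interaction = ss_cell - ss_h - ss_s,
       subject = ss_sub, total = sum((r - g)^2))
}

#' ART ANOVA with subject as an additive blocking factor
#'
#' Aligned Rank Transform factorial ANOVA for the hand x speed
#' within-subject design: for each effect, a fixed-effects factorial ANOVA
#' is run on that effect's midranks with subject entered as an additive
#' block, and only the effect of interest is reported. For a balanced
#' cohort of `n` subjects x 2 hands x 3 speeds with one observation per
#' cell, the error df is `6n - 1 - 1 - 2 - 2 - (n - 1)`; 195 for n = 40.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' The design must be balanced (equal counts in every subject x hand x
#' speed cell); the closed-form orthogonal decomposition is then exact and
#' identical to the linear-model ANOVA.
#'
#' @inheritParams align_rank_transform
#' @param subject subject column name.
#' @return data.frame with one row per effect (`hand`, `speed`,
#'   `hand:speed`) and columns `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, `degenerate` (TRUE when all ranks tie and F is
#'   undefined).
#' @export
art_anova <- function(data, response = "value", hand = "hand",
                      speed = "speed", subject = "subject") {
  if (!subject %in% names(data)) stop("missing column: ", subject)
  ar <- align_rank_transform(data, response, hand, speed)
  fh <- factor(ar[[hand]])
  fs <- factor(ar[[speed]])
  fsub <- factor(ar[[subject]])
  counts <- table(fsub, fh, fs)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0)) {
    stop("design must be balanced: equal observations in every subject x ",
         "hand x speed cell")
  }
  N <- nrow(ar)
  df_num <- c(hand = nlevels(fh) - 1L, speed = nlevels(fs) - 1L,
              interaction = (nlevels(fh) - 1L) * (nlevels(fs) - 1L))
  df_den <- N - 1L - sum(df_num) - (nlevels(fsub) - 1L)
  out <- lapply(c("hand", "speed", "interaction"), function(eff) {
    r <- ar[[paste0("rank_", eff)]]
    ss <- balanced_anova_ss(r, fh, fs, fsub)
    ss_err <- ss$total - ss$hand - ss$speed - ss$interaction - ss$subject
    ss_eff <- ss[[eff]]
    degenerate <- ss_err <= .Machine$double.eps * max(ss$total, 1)
    Fv <- if (degenerate) NaN else (ss_eff / df_num[[eff]]) / (ss_err / df_den)
    data.frame(
      effect = if (eff == "interaction") "hand:speed" else eff,
      F = Fv, df_num = df_num[[eff]], df_den = df_den,
      p = if (degenerate) NaN else stats::pf(Fv, df_num[[eff]], df_den,
                                             lower.tail = FALSE),
      partial_eta_sq = if (degenerate) NaN else ss_eff / (ss_eff + ss_err),
      degenerate = degenerate
    )
  })
  do.call(rbind, out)
}

#' Tukey HSD post hocs on ranked responses
#'
#' Studentized-range pairwise comparisons between the levels of one factor,
#' family-wise adjusted, run on the effect's (aligned-and-)ranked responses
#' as produced by [align_rank_transform()].
#'
#' @param values numeric responses (typically a `rank_*` column).
#' @param groups factor of levels being compared (>= 2 levels).
#' @return data.frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 levels")
  fit <- stats::aov(values ~ groups, data = data.frame(values = values,
                                                       groups = groups))
  tk <- stats::TukeyHSD(fit)$groups
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}
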