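#' Analyze one recording end to end
#'
#' Fixed stage order: zero-phase low-pass filter, finite-difference
#' kinematics, centroid-angle cycle segmentation, first/last cycle
#' exclusion, per-cycle features, condition summary over the retained
#' cycles. Stage failures are reported with the stage name and the
#' recording's identity.
#'
#' @param traj a [trajectory()].
#' @param config an [analysis_config()].
#' @return list with `features` (per-retained-cycle feature table, with
#'   `subject`, `hand`, `speed` prepended) and `summary` (the long
#'   [summarize_condition()] table).
#' @export
analyze_recording <- function(traj, config = analysis_config()) {
  ident <- paste(traj$subject_id, traj$hand, traj$speed, sep = "/")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("recording ", ident, ", stage ", name, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  filt <- stage("filter", lowpass_filter(traj, config$filter_cutoff,
                                         config$filter_order))
  prof <- stage("derivatives", estimate_derivatives(filt))
  cycles <- stage("segment", segment_cycles(filt))
  kept <- stage("exclude", exclude_cycles(cycles, config$exclusion[1],
                                          config$exclusion[2],
                                          config$min_cycles_after_exclusion))
  template <- template_for_hand(config$template, traj$hand)
  feats <- stage("features", do.call(rbind, lapply(seq_len(nrow(kept)),
    function(i) analyze_cycle(filt, prof, kept[i, ], template, config))))
  summ <- stage("summarize", summarize_condition(feats, traj$subject_id,
                                                 traj$hand, traj$speed))
  feats <- cbind(subject = traj$subject_id, hand = traj$hand,
                 speed = traj$speed, feats)
  list(features = feats, summary = summ)
}

#' Analyze every recording of a cohort
#'
#' Applies [analyze_recording()] to a list of trajectories. Failing
#' recordings are skipped with a message and counted.
#'
#' @param trajectories list of [trajectory()] objects.
#' @param config an [analysis_config()].
#' @return list with row-bound `features` and `summaries` tables and
#'   `n_failed`.
#' @export
analyze_cohort <- function(trajectories, config = analysis_config()) {
  res <- lapply(trajectories, function(tr) {
    tryCatch(analyze_recording(tr, config), error = function(e) {
      message("skipping recording: ", conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(res, is.null, TRUE)
  list(
    features = do.call(rbind, c(lapply(res[ok], `[[`, "features"),
                                list(make.row.names = FALSE))),
    summaries = do.call(rbind, c(lapply(res[ok], `[[`, "summary"),
                                 list(make.row.names = FALSE))),
    n_failed = sum(!ok)
  )
}

#' Cohort summary grid (parameters x conditions)
#'
#' Across-subject means and SDs of the per-recording parameter means, as a
#' 12-parameter x 6-condition grid (conditions ordered ND-S, ND-N, ND-F,
#' D-S, D-N, D-F). Missing conditions yield NA columns with a message.
#'
#' @param summaries row-bound [summarize_condition()] tables.
#' @return list with matrices `mean` and `sd` (rows = parameters, columns =
#'   conditions).
#' @export
summarize_cohort <- function(summaries) {
  conditions <- c("ND-S", "ND-N", "ND-F", "D-S", "D-N", "D-F")
  params <- feature_parameters()
  cond <- paste(summaries$hand, summaries$speed, sep = "-")
  mk <- function(fun) {
    m <- matrix(NA_real_, length(params), length(conditions),
                dimnames = list(params, conditions))
    for (p in params) for (cc in conditions) {
      v <- summaries$mean[summaries$parameter == p & cond == cc]
      if (length(v)) m[p, cc] <- fun(v)
    }
    m
  }
  out <- list(mean = mk(mean), sd = mk(stats::sd))
  if (anyNA(out$mean)) message("summary grid has missing conditions")
  out
}

#' Full statistical report for a cohort
#'
#' For each per-cycle parameter: the ART ANOVA (hand, speed, interaction)
#' on the per-recording means and on the per-recording CVs; the cross-hand
#' accuracy and precision correlations at each speed; and pairwise Steiger
#' comparisons of the three per-speed correlations (non-overlapping
#' variant, cross-correlations estimated from the cohort). Subjects without
#' all six conditions are dropped listwise with a message.
#'
#' @param summaries row-bound [summarize_condition()] tables.
#' @param parameters parameters to analyze.
#' @return a list of class `stat_report`, one element per parameter, each
#'   with `anova_mean`, `anova_cv`, `accuracy`, `precision`,
#'   `steiger_accuracy`, `steiger_precision`.
#' @export
run_statistics <- function(summaries, parameters = feature_parameters()) {
  cond_count <- table(unique(summaries[, c("subject", "hand", "speed")])$subject)
  complete <- names(cond_count)[cond_count == 6L]
  dropped <- setdiff(unique(summaries$subject), complete)
  if (length(dropped)) {
    message("dropping ", length(dropped), " incomplete subject(s) listwise")
  }
  if (length(complete) < 3L) stop("too few subjects: need at least 3 with ",
                                  "all six conditions")
  summaries <- summaries[summaries$subject %in% complete, ]
  speeds <- c("S", "N", "F")
  report <- lapply(parameters, function(p) {
    sub <- summaries[summaries$parameter == p, ]
    res <- list(
      anova_mean = art_anova(sub, response = "mean"),
      anova_cv = art_anova(sub, response = "cv"),
      accuracy = lapply(stats::setNames(speeds, speeds), function(sp)
        correlation_accuracy(summaries, p, sp)),
      precision = lapply(stats::setNames(speeds, speeds), function(sp)
        correlation_precision(summaries, p, sp))
    )
    res$steiger_accuracy <- steiger_speed_pairs(sub, "mean")
    res$steiger_precision <- steiger_speed_pairs(sub, "cv")
    res
  })
  structure(stats::setNames(report, parameters), class = "stat_report")
}

# pairwise Steiger comparisons of the per-speed D-ND correlations of one
# parameter; the six cross-correlations of each quadruple are estimated
# from the subject-aligned data
steiger_speed_pairs <- function(param_summaries, statistic = c("mean", "cv")) {
  statistic <- match.arg(statistic)
  speeds <- c("S", "N", "F")
  vecs <- lapply(stats::setNames(speeds, speeds), function(sp)
    cross_hand_vectors(param_summaries, param_summaries$parameter[1], sp,
                       statistic))
  pairs <- utils::combn(speeds, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    v1 <- vecs[[pr[1]]]; v2 <- vecs[[pr[2]]]
    common <- intersect(v1$subjects, v2$subjects)
    a <- v1$D[match(common, v1$subjects)]; b <- v1$ND[match(common, v1$subjects)]
    cc <- v2$D[match(common, v2$subjects)]; d <- v2$ND[match(common, v2$subjects)]
    st <- steiger_test(stats::cor(a, b), stats::cor(cc, d), n = length(common),
                       cross = c(stats::cor(a, cc), stats::cor(a, d),
                                 stats::cor(b, cc), stats::cor(b, d)))
    data.frame(comparison = paste(pr, collapse = " vs "), Z = st$Z, p = st$p)
  })
  do.call(rbind, out)
}

#' @export
print.stat_report <- function(x, ...) {
  for (p in names(x)) {
    cat("==", p, "==\n")
    am <- x[[p]]$anova_mean
    for (i in seq_len(nrow(am))) {
      cat(sprintf("  mean  %-10s F(%d, %d) = %.2f, p = %.4g, pes = %.3f\n",
                  am$effect[i], am$df_num[i], am$df_den[i], am$F[i], am$p[i],
                  am$partial_eta_sq[i]))
    }
    acc <- x[[p]]$accuracy
    cat(sprintf("  accuracy r (S/N/F): %.3f / %.3f / %.3f\n",
                acc$S$r, acc$N$r, acc$F$r))
  }
  invisible(x)
}

#' Write a run manifest
#'
#' JSON record of a pipeline run: configuration snapshot, seed, inputs,
#' package version, timestamp, and per-stage record counts.
#'
#' @param path output file.
#' @param config the [analysis_config()] used.
#' @param seed the run seed.
#' @param inputs character vector of input identifiers.
#' @param counts named list/vector of per-stage record counts.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, inputs = character(),
                               counts = list()) {
  manifest <- list(
    package = "ellipsekin",
    version = as.character(utils::packageVersion("ellipsekin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass_deep(config),
    inputs = inputs,
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
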