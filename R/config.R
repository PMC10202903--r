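#' Template ellipse specification
#'
#' The template traced by the subjects: semi-major axis 8 cm, semi-minor
#' 2 cm (eccentricity 0.968), rotated +45 degrees for right-hand (dominant,
#' counterclockwise) and -45 degrees for left-hand (non-dominant, clockwise)
#' drawing.
#'
#' @param a,b semi-major and semi-minor axes in cm (`a >= b > 0`).
#' @param rotation major-axis inclination, degrees counterclockwise from the
#'   +x axis, in (-90, 90].
#' @param center numeric length-2, ellipse center in cm.
#' @param direction tracing direction, `"CCW"` or `"CW"`.
#' @return list of class `template_spec`.
#' @export
template_spec <- function(a = 8, b = 2, rotation = 45, center = c(0, 0),
                          direction = c("CCW", "CW")) {
  direction <- match.arg(direction)
  if (!(is.numeric(a) && is.numeric(b) && b > 0 && a >= b)) {
    stop("template requires a >= b > 0")
  }
  if (rotation <= -90 || rotation > 90) stop("rotation must lie in (-90, 90]")
  structure(list(a = a, b = b, rotation = rotation,
                 center = as.numeric(center), direction = direction),
            class = "template_spec")
}

#' Hand-specific template
#'
#' Returns the template as traced by a given hand: the right (dominant) hand
#' traces the +45 degree template counterclockwise, the left (non-dominant)
#' hand the -45 degree template clockwise.
#'
#' @param template a [template_spec()].
#' @param hand `"D"` or `"ND"`.
#' @export
template_for_hand <- function(template = template_spec(), hand = c("D", "ND")) {
  hand <- match.arg(hand)
  if (hand == "D") return(template)
  template_spec(a = template$a, b = template$b, rotation = -template$rotation,
                center = template$center, direction = "CW")
}

#' Analysis configuration
#'
#' Bundles every tunable of the processing pipeline. Defaults encode the
#' study's analysis choices: a zero-phase low-pass Butterworth filter at
#' 7 Hz (order 2), exclusion of the first and the last two drawn ellipses,
#' and numerical floors for the log-domain power-law fit.
#'
#' @param filter_cutoff low-pass cutoff in Hz; must be below the Nyquist
#'   frequency of the data it is applied to.
#' @param filter_order Butterworth order.
#' @param exclusion integer length-2 `(n_first, n_last)`: cycles dropped at
#'   the start and end of each recording.
#' @param min_cycles_after_exclusion minimum retained cycles (>= 2).
#' @param speed_epsilon tangential-speed floor (cm/s) below which samples are
#'   masked out of the log-log fit.
#' @param curvature_epsilon curvature floor (1/cm) for the same mask.
#' @param seed integer seed for anything stochastic downstream.
#' @param template the [template_spec()] used for relative size.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(filter_cutoff = 7, filter_order = 2,
                            exclusion = c(1, 2),
                            min_cycles_after_exclusion = 2,
                            speed_epsilon = 1e-6, curvature_epsilon = 1e-6,
                            seed = 1L, template = template_spec()) {
  if (!is.finite(filter_cutoff) || filter_cutoff <= 0) {
    stop("filter_cutoff must be positive (field: filter_cutoff)")
  }
  if (filter_order < 1) stop("filter_order must be >= 1 (field: filter_order)")
  exclusion <- as.integer(exclusion)
  if (length(exclusion) != 2L || any(exclusion < 0)) {
    stop("exclusion must be two non-negative counts (field: exclusion)")
  }
  if (min_cycles_after_exclusion < 2) {
    stop("min_cycles_after_exclusion must be >= 2 (field: min_cycles_after_exclusion)")
  }
  if (speed_epsilon < 0) stop("speed_epsilon must be >= 0 (field: speed_epsilon)")
  if (curvature_epsilon < 0) stop("curvature_epsilon must be >= 0 (field: curvature_epsilon)")
  if (!inherits(template, "template_spec")) stop("template must be a template_spec")
  structure(list(
    filter_cutoff = filter_cutoff, filter_order = as.integer(filter_order),
    exclusion = exclusion,
    min_cycles_after_exclusion = as.integer(min_cycles_after_exclusion),
    speed_epsilon = speed_epsilon, curvature_epsilon = curvature_epsilon,
    seed = as.integer(seed), template = template
  ), class = "analysis_config")
}

#' Load an analysis configuration from YAML or JSON
#'
#' Any omitted field takes its [analysis_config()] default; an empty document
#' yields the full default configuration. The template block accepts fields
#' `a`, `b`, `rotation`, `center`, `direction`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` document.
#' @return an [analysis_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  known <- c("filter_cutoff", "filter_order", "exclusion",
             "min_cycles_after_exclusion", "speed_epsilon",
             "curvature_epsilon", "seed", "template")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  args <- doc[setdiff(names(doc), "template")]
  if (!is.null(doc$template)) {
    args$template <- do.call(template_spec, as.list(doc$template))
  }
  do.call(analysis_config, args)
}
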