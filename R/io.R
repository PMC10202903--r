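#' Read a pen trajectory from a delimited text file
#'
#' The on-disk format is comma-separated with a `t,x,y` header and
#' `#`-prefixed metadata lines (`# subject:`, `# hand:`, `# speed:`,
#' `# sample_rate:`, `# units:`). Positions declared in mm are converted to
#' cm. Recordings whose time gaps exceed the 10% uniformity tolerance are
#' linearly resampled to a uniform grid, with a message.
#'
#' @param path file to read.
#' @param subject_id,hand,speed optional label overrides; when `NULL` the
#'   file's metadata (or defaults `anon`/`D`/`N`) are used.
#' @return a validated [trajectory()].
#' @seealso [write_trajectory_table()]
#' @export
read_trajectory_table <- function(path, subject_id = NULL, hand = NULL,
                                  speed = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)\\s*$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("format error: no data rows in ", path)
  dat <- utils::read.csv(text = body, header = TRUE)
  for (col in c("t", "x", "y")) {
    if (!col %in% names(dat)) stop("format error: missing column '", col, "' in ", path)
    if (!is.numeric(dat[[col]])) stop("format error: column '", col, "' is not numeric in ", path)
  }
  units <- tolower(meta$units %||% "cm")
  if (units == "mm") {
    dat$x <- dat$x / 10
    dat$y <- dat$y / 10
  } else if (units != "cm") {
    stop("format error: unsupported units '", units, "'")
  }
  rate <- as.numeric(meta$sample_rate %||% NA)
  if (!is.finite(rate)) {
    dt <- stats::median(diff(dat$t))
    if (!is.finite(dt) || dt <= 0) stop("validation error: t is not increasing")
    rate <- 1 / dt
  }
  bad <- which(diff(dat$t) <= 0)
  if (length(bad)) {
    stop("validation error: t not strictly increasing at row ", bad[1] + 1L)
  }
  args <- list(
    t = dat$t, x = dat$x, y = dat$y,
    subject_id = subject_id %||% meta$subject %||% "anon",
    hand = hand %||% meta$hand %||% "D",
    speed = speed %||% meta$speed %||% "N",
    sample_rate = rate
  )
  tr <- tryCatch(do.call(trajectory, args), error = function(e) e)
  if (inherits(tr, "error")) {
    if (grepl("sampling gap", conditionMessage(tr))) {
      message("non-uniform sampling in ", basename(path),
              "; resampling to a uniform ", signif(rate, 6), " Hz grid")
      raw <- structure(list(subject_id = args$subject_id, hand = args$hand,
                            speed = args$speed, sample_rate = rate,
                            samples = data.frame(t = dat$t, x = dat$x, y = dat$y)),
                       class = "trajectory")
      tr <- regularize_trajectory(raw)
    } else {
      stop(tr)
    }
  }
  tr
}

#' Write a trajectory to delimited text
#'
#' Writes the comma-separated `t,x,y` table preceded by `#` metadata lines,
#' re-readable by [read_trajectory_table()]. Positions are written in cm
#' with enough digits for 1e-9 round-trip fidelity.
#'
#' @param traj a valid [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(traj, path) {
  validate_trajectory(traj)
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(c(
    paste0("# subject: ", traj$subject_id),
    paste0("# hand: ", traj$hand),
    paste0("# speed: ", traj$speed),
    paste0("# sample_rate: ", format(traj$sample_rate, digits = 12)),
    "# units: cm",
    "t,x,y"
  ), con)
  s <- traj$samples
  writeLines(sprintf("%.12g,%.12g,%.12g", s$t, s$x, s$y), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
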