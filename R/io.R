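# Tabular input/output: trajectories and summaries as delimited text,
# run manifests as JSON, and a tolerant reader for external two-column
# time series.

#' Write a trajectory as delimited text (plus optional JSON manifest)
#'
#' The table has a header, first column `time_h`, one column per state
#' variable. With `manifest = TRUE` a sidecar `<path>.json` records the
#' parameter set, system type and solver options needed to regenerate the
#' run exactly.
#'
#' @param traj A `per2_trajectory`.
#' @param path Output file path (CSV).
#' @param manifest Also write `<path>.json`?
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, manifest = FALSE) {
  if (!inherits(traj, "per2_trajectory"))
    abort_domain("traj must be a per2_trajectory")
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (manifest) {
    m <- list(params = unclass(attr(traj, "params"))[.param_fields],
              system = attr(traj, "system"),
              solver = attr(traj, "solver"),
              package_version = as.character(utils::packageVersion("per2as")))
    jsonlite::write_json(m, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write an oscillation summary as CSV and/or JSON
#'
#' @param summary A `per2_summary` (see [oscillation_summary()]).
#' @param path Output path; a `.json` extension selects JSON, anything
#'   else a flat CSV with one row per variable.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(summary), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an external two-column time series
#'
#' Accepts delimited text (comma, tab or whitespace separated, with or
#' without a header) whose first two columns are time (hours) and value.
#' Malformed lines raise a parse error naming the offending line number.
#'
#' @param path File path.
#' @return Data frame with columns `time_h` and `value`, usable by every
#'   metrics function.
#' @export
read_series <- function(path) {
  if (!file.exists(path))
    abort_domain(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(errorCondition(sprintf("'%s': need at least 2 data lines", path),
                        class = c("per2as_parse_error", "error")))
  sep <- if (grepl(",", lines[[2L]])) "," else if (grepl("\t", lines[[2L]]))
    "\t" else "[[:space:]]+"
  split1 <- strsplit(trimws(lines[[1L]]), sep)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(split1[1:2])))
  start <- if (has_header) 2L else 1L
  tt <- numeric(0); vv <- numeric(0)
  for (i in start:length(lines)) {
    fields <- strsplit(trimws(lines[[i]]), sep)[[1L]]
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (length(fields) < 2L || anyNA(vals))
      stop(errorCondition(
        sprintf("'%s': cannot parse line %d as (time, value): \"%s\"",
                path, i, lines[[i]]),
        class = c("per2as_parse_error", "error")))
    tt <- c(tt, vals[[1L]]); vv <- c(vv, vals[[2L]])
  }
  if (any(diff(tt) <= 0))
    stop(errorCondition(
      sprintf("'%s': time column is not strictly increasing", path),
      class = c("per2as_parse_error", "error")))
  data.frame(time_h = tt, value = vv)
}
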