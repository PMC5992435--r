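#' Write a run's per-tick trajectory to CSV
#'
#' Fixed column order: `tick`, the four breed proportions, the four
#' within-culture changes, the six pairwise similarities (pairs in canonical
#' breed order).
#'
#' @param run A `margin_run` created with `trajectory = TRUE`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  stopifnot(inherits(run, "margin_run"))
  if (is.null(run$records)) {
    stop("run was executed without trajectory = TRUE")
  }
  write.csv(run$records, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a design's run-summary table
#'
#' One row per run: condition labels, replicate, seed and the 14
#' time-averaged dependent variables.
#'
#' @param design A `margin_design`.
#' @param path CSV file path.
#' @return `path` (write) or a `margin_design` data frame (read), with the
#'   provenance manifest stored alongside as `<path>.manifest.json` on write
#'   and restored on read when present.
#' @export
write_summaries_csv <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE)
  man <- attr(design, "manifest")
  if (!is.null(man)) {
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_summaries_csv
#' @export
read_summaries_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  man_path <- paste0(path, ".manifest.json")
  if (file.exists(man_path)) {
    attr(d, "manifest") <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  }
  class(d) <- c("margin_design", "data.frame")
  d
}

#' Write one ANOVA report (CSV + text block)
#'
#' Writes `anova_<dv>.csv` (machine-readable effect table with Tukey rows
#' appended) and `anova_<dv>.txt` (the printed summary) into `dir`.
#'
#' @param x A `margin_anova`.
#' @param dir Output directory (created if needed).
#' @return The CSV path, invisibly.
#' @export
write_anova_report <- function(x, dir) {
  stopifnot(inherits(x, "margin_anova"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0("anova_", x$dv, ".csv"))
  eff <- x$effects
  eff$dv <- x$dv
  write.csv(eff, csv, row.names = FALSE)
  txt <- file.path(dir, paste0("anova_", x$dv, ".txt"))
  con <- file(txt, open = "wt")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  summary(x)
  invisible(csv)
}
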