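#' Stage-by-stage attrition report
#'
#' The pipeline's accounting object: an ordered table of filter stages,
#' each with the denominator its percent is computed against, the count
#' removed, and the count remaining after the stage. Percentages follow
#' the reporting convention of EST SNP surveys: nearest integer, except
#' one decimal place when the value is below 2% (so small classes print
#' as e.g. `0.2%` rather than `0%`).
#'
#' @param stage Character vector of stage names.
#' @param denominator Integer vector: the count each stage's percent is
#'   relative to (conventionally the count entering the cascade).
#' @param removed Integer vector of counts removed at each stage.
#' @param remaining Integer vector of counts remaining after each stage.
#' @return Object of class `attrition_report` (a data.frame with an
#'   additional `percent` character column).
#' @examples
#' attrition_report("indel", 42147L, 2179L, 39968L)
#' @export
attrition_report <- function(stage, denominator, removed, remaining) {
  stopifnot(length(stage) == length(removed),
            length(stage) == length(remaining),
            length(stage) == length(denominator))
  if (any(removed < 0) || any(remaining < 0)) {
    stop("removed and remaining must be non-negative", call. = FALSE)
  }
  df <- data.frame(stage = as.character(stage),
                   denominator = as.integer(denominator),
                   removed = as.integer(removed),
                   remaining = as.integer(remaining),
                   stringsAsFactors = FALSE)
  df$percent <- mapply(format_percent, df$removed, df$denominator)
  class(df) <- c("attrition_report", "data.frame")
  df
}

#' Format a removal percentage
#'
#' Nearest integer, with one decimal when the value is below 2%.
#' A zero denominator formats as `0.0`.
#'
#' @param removed,denominator Counts.
#' @return Character scalar, without the `%` sign.
#' @export
format_percent <- function(removed, denominator) {
  pct <- if (denominator > 0) 100 * removed / denominator else 0
  if (pct < 2) sprintf("%.1f", round(pct, 1)) else
    sprintf("%d", round(pct))
}

#' Format a removal count with its percentage
#'
#' Renders `"2,179 (5%)"`-style fragments: thousands separators on the
#' count, percent per [format_percent()].
#'
#' @param removed,denominator Counts.
#' @return Character scalar.
#' @examples
#' format_count_pct(2179, 42147)   # "2,179 (5%)"
#' @export
format_count_pct <- function(removed, denominator) {
  sprintf("%s (%s%%)", format(removed, big.mark = ",", scientific = FALSE),
          format_percent(removed, denominator))
}

#' Render an attrition report as text or TSV
#'
#' The text form prints one narrative line per stage
#' (`stage: N (P%) removed, M remaining`); the TSV form is
#' machine-readable with columns `stage`, `denominator`, `removed`,
#' `remaining`, `percent`. Every number in the text form equals the
#' corresponding TSV field.
#'
#' @param report An [attrition_report()].
#' @param format `"text"` or `"tsv"`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
render_report <- function(report, format = c("text", "tsv"), path = NULL) {
  stopifnot(inherits(report, "attrition_report"))
  format <- match.arg(format)
  if (format == "text") {
    lines <- sprintf(
      "%s: %s removed, %s remaining",
      report$stage,
      mapply(format_count_pct, report$removed, report$denominator),
      format(report$remaining, big.mark = ",", trim = TRUE))
  } else {
    lines <- c(paste(c("stage", "denominator", "removed", "remaining",
                       "percent"), collapse = "\t"),
               sprintf("%s\t%d\t%d\t%d\t%s", report$stage,
                       report$denominator, report$removed,
                       report$remaining, report$percent))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.attrition_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
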