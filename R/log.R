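#' Append a line to a run log
#'
#' The pipeline keeps an append-only plain-text log with ISO-8601 timestamps
#' so that each processing decision (day parsing, geometry repair, trimming,
#' registration scores, detected movements) is traceable after the fact.
#'
#' @param path Log file path, or `NULL` to skip logging.
#' @param ... Message parts, pasted together with no separator.
#' @return Invisibly, the formatted line (or `NULL` when `path` is `NULL`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".log")
#' run_log(f, "stage harmonize: trimmed 4 slices")
#' readLines(f)
run_log <- function(path, ...) {
  if (is.null(path)) {
    return(invisible(NULL))
  }
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", paste0(..., collapse = ""))
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}
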