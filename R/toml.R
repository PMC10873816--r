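#' Read a minimal TOML file
#'
#' Parses the flat key/value subset of TOML used by per-timepoint
#' `geometry.toml` metadata: bare keys assigned scalars (number, boolean,
#' quoted string) or arrays of numbers. Comments (`#`) and blank lines are
#' ignored; table headers and nested structures are rejected.
#'
#' @param path Path to the file.
#' @return Named list of parsed values.
#' @seealso [write_toml()], [load_geometry()]
#' @export
read_toml <- function(path) {
  if (!file.exists(path)) {
    stop("TOML file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      stop("TOML parse error at line ", i, ": table headers are not supported (", lines[[i]], ")")
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) {
      stop("TOML parse error at line ", i, ": expected 'key = value', got '", lines[[i]], "'")
    }
    out[[m[[2]]]] <- parse_toml_value(m[[3]], i)
  }
  out
}

parse_toml_value <- function(value, line_no) {
  value <- trimws(value)
  if (grepl("^\\[", value)) {
    if (!grepl("\\]$", value)) {
      stop("TOML parse error at line ", line_no, ": unterminated array")
    }
    inner <- trimws(substr(value, 2, nchar(value) - 1))
    if (!nzchar(inner)) {
      return(numeric(0))
    }
    parts <- trimws(strsplit(inner, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (anyNA(nums)) {
      stop("TOML parse error at line ", line_no, ": non-numeric array element")
    }
    return(nums)
  }
  if (grepl('^".*"$', value)) {
    return(substr(value, 2, nchar(value) - 1))
  }
  if (value %in% c("true", "false")) {
    return(value == "true")
  }
  num <- suppressWarnings(as.numeric(value))
  if (is.na(num)) {
    stop("TOML parse error at line ", line_no, ": cannot parse value '", value, "'")
  }
  num
}

#' Write a minimal TOML file
#'
#' Inverse of [read_toml()] for the same flat subset.
#'
#' @param x Named list of scalars, numeric vectors, or strings.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_toml <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  fmt <- function(v) {
    if (is.character(v)) {
      paste0('"', v, '"')
    } else if (is.logical(v)) {
      ifelse(v, "true", "false")
    } else if (length(v) > 1) {
      paste0("[", paste(format(v, digits = 15, trim = TRUE, scientific = FALSE), collapse = ", "), "]")
    } else {
      format(v, digits = 15, trim = TRUE, scientific = FALSE)
    }
  }
  lines <- vapply(names(x), function(k) paste0(k, " = ", fmt(x[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}
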