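#' Read and write trial-level tables
#'
#' `read_trials()` reads a delimited text file (comma, semicolon or
#' tab; sniffed from the header line unless `delim` is given) with the
#' trial-record columns `subject`, `block`, `trial`, `distractor`,
#' `rt`, `error` (plus optional `valence`, `arousal`), coercing the
#' two flags from 0/1 or TRUE/FALSE. `write_trials()` writes a table
#' in the same schema as CSV, so a written table reads back
#' identically.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) sniffs it from the
#'   header line.
#' @return `read_trials()` returns a validated tibble;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("Input file not found: %s", path), call. = FALSE)
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t"
    else if (grepl(";", header)) ";"
    else ","
  }
  trials <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
  for (flag in c("distractor", "error")) {
    if (flag %in% names(trials) && !is.logical(trials[[flag]])) {
      trials[[flag]] <- as.logical(as.numeric(trials[[flag]]))
    }
  }
  check_trials(trials)
  trials
}

#' @rdname read_trials
#' @param trials A trial table.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Serialize an analysis report to JSON
#'
#' Writes any of the package's result objects (lists of tibbles,
#' [run_end_to_end()] bundles, correlation tables) as JSON with a
#' schema version stamp. Data frames become arrays of row objects;
#' scalars are unboxed.
#'
#' @param report A list or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(schema = "conflictadapt/1", report = strip_classes(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (inherits(x, "ca_dissociability") || inherits(x, "ca_anova")) {
    x <- unclass(x)
  }
  if (is.list(x)) return(lapply(x, strip_classes))
  x
}
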