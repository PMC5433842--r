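#' Read a key-value configuration file
#'
#' Plain-text `key = value` (or `key: value`) pairs, one per line; `#`
#' comments and blank lines ignored. Values that parse as numbers become
#' numeric; comma-separated values become vectors. The result can be
#' spliced into [design_config()] or other constructors with `do.call()`.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L) abort(sprintf("cannot parse config line: %s", ln))
    key <- trimws(m[2L])
    vals <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}
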