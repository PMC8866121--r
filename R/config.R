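#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that
#' parse as numbers become numeric; comma-separated values become
#' vectors. Recognised keys mirror the arguments of
#' [run_trap_search()] plus `peptide`, `dap_position`, `input`, `out`
#' and `seed`.
#'
#' @param path Config file path.
#' @return Named list of typed values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line: '", lines[which(bad)[1]], "'")
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  out <- lapply(vals, function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(num))) num else parts
  })
  names(out) <- keys
  out
}
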