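`%||%` <- function(x, y) if (is.null(x)) y else x

#' Managed work directory
#'
#' Intermediate files produced by compiled pipelines live in a single managed
#' directory; only outputs named via [out()] escape it. The directory is
#' configurable per call or globally via `options(typedflow.workdir = ...)`.
#'
#' @param path New work directory (optional). When given, the option is set
#'   and the previous value returned invisibly.
#' @return The current work directory path.
#' @export
tf_workdir <- function(path = NULL) {
  if (!is.null(path)) {
    old <- getOption("typedflow.workdir", "_typedflow")
    options(typedflow.workdir = path)
    return(invisible(old))
  }
  getOption("typedflow.workdir", "_typedflow")
}

# Classed conditions so callers can distinguish failure modes programmatically.
tf_stop <- function(class, fmt, ..., call. = FALSE) {
  stop(structure(
    class = c(paste0("tf_", class), "tf_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Locale-independent ordering used everywhere determinism matters.
tf_sort <- function(x) sort(x, method = "radix")

tf_order <- function(...) order(..., method = "radix")

# Write lines atomically: temp file in the same directory, then rename.
write_lines_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

toytool_path <- function() {
  p <- system.file("tools", "toytool.R", package = "typedflow")
  if (!nzchar(p)) tf_stop("internal", "toytool script not found in installed package")
  p
}
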