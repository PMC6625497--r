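# Execution platform abstraction. Builders never spawn processes directly:
# they call run_command() on the executor handle they receive, so the same
# workflow runs locally or via generated cluster job scripts without any
# change to stage definitions.

#' Local executor
#'
#' Spawns the command directly; each token is one argv element (no shell
#' interpretation). Non-zero exit raises an error.
#'
#' @param log_file Optional file capturing combined stdout/stderr of
#'   commands; default discards.
#' @return A `tf_executor` of kind `"local"`.
#' @export
local_executor <- function(log_file = NULL) {
  structure(list(kind = "local", config = list(log_file = log_file)),
            class = "tf_executor")
}

#' Script (cluster) executor
#'
#' Writes each command into a POSIX shell job script carrying Torque-style
#' resource headers (`#PBS -l nodes=1:ppn=<threads>,mem=<mem>mb[,walltime=...]`,
#' optionally `#PBS -q <queue>`). In `"dry"` mode (the default) the script is
#' executed locally immediately after being written, so the full script
#' generation code path is exercised with no scheduler present. In
#' `"submit"` mode the configured submit command is invoked on the script
#' and completion is detected by polling a sentinel file the script touches
#' on success.
#'
#' @param script_dir Directory receiving job scripts.
#' @param mode `"dry"` or `"submit"`.
#' @param submit_cmd Submit command (e.g. `"qsub"`), required for
#'   `"submit"` mode.
#' @param default_resources Resource defaults merged under per-call
#'   requests: `threads`, `memory_mb`, optional `walltime_s`, `queue`.
#' @param poll_interval_s,timeout_s Sentinel polling controls for submit
#'   mode.
#' @return A `tf_executor` of kind `"script"`.
#' @export
script_executor <- function(script_dir = file.path(tf_workdir(), "jobs"),
                            mode = c("dry", "submit"), submit_cmd = NULL,
                            default_resources = list(threads = 1L, memory_mb = 1024L),
                            poll_interval_s = 1, timeout_s = 3600) {
  mode <- match.arg(mode)
  if (mode == "submit" && is.null(submit_cmd))
    tf_stop("construction", "submit mode needs a submit_cmd")
  structure(list(kind = "script",
                 config = list(script_dir = script_dir, mode = mode,
                               submit_cmd = submit_cmd,
                               default_resources = default_resources,
                               poll_interval_s = poll_interval_s,
                               timeout_s = timeout_s)),
            class = "tf_executor")
}

#' Run a command through an executor
#'
#' The framework's single process boundary. `tokens` is an argv vector --
#' the first element the executable, the rest its arguments -- passed
#' without shell interpretation.
#'
#' @param executor A `tf_executor`.
#' @param tokens Non-empty character vector of command tokens.
#' @param resources Named list: `threads`, `memory_mb`, optional
#'   `walltime_s`, `queue`. Used for job script headers; ignored by the
#'   local executor.
#' @param id Short identifier used in job script names and error messages.
#' @return Invisibly `TRUE` on success; errors otherwise.
#' @export
run_command <- function(executor, tokens, resources = list(), id = "job") {
  stopifnot(inherits(executor, "tf_executor"))
  tokens <- as.character(tokens)
  if (!length(tokens) || any(!nzchar(tokens)))
    tf_stop("construction", "run_command needs a non-empty token sequence")
  switch(executor$kind,
         local = run_local(executor, tokens, id),
         script = run_script(executor, tokens, resources, id),
         tf_stop("construction", "unknown executor kind '%s'", executor$kind))
}

run_local <- function(executor, tokens, id) {
  logf <- executor$config$log_file
  if (Sys.which(tokens[1]) == "" && !file.exists(tokens[1]))
    tf_stop("missing_executable", "[%s] executable not found: %s", id, tokens[1])
  out <- suppressWarnings(system2(tokens[1], shQuote(tokens[-1]),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (!is.null(logf)) {
    dir.create(dirname(logf), recursive = TRUE, showWarnings = FALSE)
    cat(paste0(out, "\n", collapse = ""), file = logf, append = TRUE)
  }
  if (status != 0L)
    tf_stop("command_failed", "[%s] command failed (exit %d): %s\n%s", id,
            status, paste(tokens, collapse = " "),
            paste(utils::tail(out, 20), collapse = "\n"))
  invisible(TRUE)
}

render_pbs_headers <- function(resources) {
  threads <- as.integer(resources$threads %||% 1L)
  mem <- as.integer(resources$memory_mb %||% 1024L)
  l <- sprintf("#PBS -l nodes=1:ppn=%d,mem=%dmb", threads, mem)
  if (!is.null(resources$walltime_s)) {
    w <- as.integer(resources$walltime_s)
    l <- sprintf("%s,walltime=%02d:%02d:%02d", l,
                 w %/% 3600L, (w %% 3600L) %/% 60L, w %% 60L)
  }
  headers <- l
  if (!is.null(resources$queue))
    headers <- c(headers, sprintf("#PBS -q %s", resources$queue))
  headers
}

run_script <- function(executor, tokens, resources, id) {
  cfg <- executor$config
  res <- utils::modifyList(cfg$default_resources, resources)
  dir.create(cfg$script_dir, recursive = TRUE, showWarnings = FALSE)
  stampsrc <- paste(c(id, tokens), collapse = "\x1f")
  stamp <- substr(digest::digest(stampsrc, algo = "sha1", serialize = FALSE), 1, 12)
  script <- file.path(cfg$script_dir, sprintf("%s-%s.sh", gsub("[^A-Za-z0-9_-]", "_", id), stamp))
  sentinel <- paste0(script, ".done")
  unlink(sentinel)
  writeLines(c(
    "#!/bin/sh",
    render_pbs_headers(res),
    "set -e",
    paste(shQuote(tokens), collapse = " "),
    paste("touch", shQuote(sentinel))
  ), script)
  Sys.chmod(script, "0755")
  if (cfg$mode == "dry") {
    out <- suppressWarnings(system2("sh", shQuote(script), stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L)
      tf_stop("command_failed", "[%s] job script failed (exit %d): %s\n%s", id,
              status, script, paste(utils::tail(out, 20), collapse = "\n"))
  } else {
    status <- suppressWarnings(system2(cfg$submit_cmd, shQuote(script)))
    if (status != 0L)
      tf_stop("command_failed", "[%s] submit command failed (exit %d)", id, status)
    waited <- 0
    while (!file.exists(sentinel)) {
      Sys.sleep(cfg$poll_interval_s)
      waited <- waited + cfg$poll_interval_s
      if (waited > cfg$timeout_s)
        tf_stop("walltime_timeout", "[%s] no completion sentinel after %ds: %s",
                id, cfg$timeout_s, script)
    }
  }
  if (!file.exists(sentinel))
    tf_stop("command_failed", "[%s] job script did not reach completion: %s", id, script)
  invisible(TRUE)
}
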