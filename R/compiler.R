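# Whole-pipeline validation (the pre-execution analogue of compile-time type
# checking) and compilation to deduplicated build rules.

new_diagnostic <- function(severity, stage_path, missing_tags, message) {
  structure(list(severity = severity, stage_path = stage_path,
                 missing_tags = missing_tags, message = message),
            class = "tf_diagnostic")
}

#' @export
format.tf_diagnostic <- function(x, ...) {
  sprintf("[%s] at [%s]: %s", x$severity,
          paste(x$stage_path, collapse = " -> "), x$message)
}

#' @export
print.tf_diagnostic <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Render diagnostics as JSON
#'
#' @param diags List of diagnostics from [validate()].
#' @return A JSON string (array of objects with `severity`, `stage_path`,
#'   `missing_tags`, `message`).
#' @export
diagnostics_json <- function(diags) {
  jsonlite::toJSON(lapply(diags, function(d) {
    list(severity = jsonlite::unbox(d$severity),
         stage_path = as.character(d$stage_path),
         missing_tags = as.character(d$missing_tags),
         message = jsonlite::unbox(d$message))
  }), auto_unbox = FALSE)
}

# stage names source -> node, disambiguated by position on repeats
numbered_stage_path <- function(expr) {
  p <- stage_path(expr)
  if (!length(p)) return(p)
  dup <- stats::ave(seq_along(p), p, FUN = seq_along)
  ifelse(p %in% p[duplicated(p)], paste0(p, "#", dup), p)
}

#' Validate pipeline expressions
#'
#' The single checking gate. For every composed node, verifies that the
#' stage's required tags are all held by the upstream expression's effective
#' tags; all violations are reported, not just the first. Also checks for
#' managed-path collisions between distinct nodes and for conflicting
#' valued-tag settings inside bundles. An empty result means the workflow is
#' well-tagged and may be compiled.
#'
#' @param exprs A pipeline expression or list of them.
#' @param workdir Managed work directory (used for collision checking).
#' @return List of `tf_diagnostic` objects (empty when valid).
#' @export
validate <- function(exprs, workdir = tf_workdir()) {
  if (is_expr(exprs)) exprs <- list(exprs)
  diags <- list()
  add <- function(d) diags[[length(diags) + 1L]] <<- d
  path_owner <- new.env(parent = emptyenv())

  check_expr <- function(e) {
    switch(class(e)[1],
      tf_source = invisible(NULL),
      tf_compose = {
        check_expr(e$upstream)
        up_tags <- effective_tags(e$upstream)
        missing <- setdiff(e$stage$required_tags, up_tags)
        if (length(missing)) {
          add(new_diagnostic(
            "error", numbered_stage_path(e), missing,
            sprintf("stage '%s' requires tag(s) {%s} not provided upstream (upstream has {%s})",
                    e$stage$name, paste(missing, collapse = ", "),
                    paste(up_tags, collapse = ", "))))
        }
        key <- paste(c(e$stage$name, expr_relpaths(e)), collapse = "\x1f")
        for (p in expr_relpaths(e)) {
          owner <- path_owner[[p]]
          if (is.null(owner)) assign(p, key, envir = path_owner)
          else if (!identical(owner, key)) {
            add(new_diagnostic(
              "error", numbered_stage_path(e), character(),
              sprintf("managed path collision on '%s' between distinct nodes", p)))
          }
        }
      },
      tf_allof = {
        for (p in e$parts) check_expr(p)
        algebra <- expr_algebra(e)
        for (vt in valued_tags(algebra)) {
          tryCatch(find_valued(e, vt), tf_value_conflict = function(cnd) {
            add(new_diagnostic("error", numbered_stage_path(e), character(),
                               conditionMessage(cnd)))
          })
        }
      },
      tf_slice = check_expr(e$parent),
      tf_out = check_expr(e$expr),
      tf_stop("internal", "not a pipeline expression")
    )
  }
  for (e in exprs) check_expr(e)
  diags
}

#' Keep only error-severity diagnostics
#'
#' @param diags List of diagnostics from [validate()].
#' @return The subset with severity `"error"`.
#' @export
validation_errors <- function(diags) {
  Filter(function(d) identical(d$severity, "error"), diags)
}

#' Create a compilation state
#'
#' Tracks the output-path sequences already compiled so that shared pipeline
#' prefixes -- the same preprocessing feeding different downstream analyses,
#' possibly across several [compile()] calls -- emit their rules exactly
#' once.
#'
#' @return A `tf_compile_state`.
#' @export
compile_state <- function() {
  structure(list(seen = new.env(parent = emptyenv())),
            class = "tf_compile_state")
}

new_ruleset <- function() {
  structure(list(rules = list(), pattern_rules = list(), wanted = character()),
            class = "tf_ruleset")
}

#' @export
print.tf_ruleset <- function(x, ...) {
  cat(sprintf("<ruleset> %d rules, %d pattern rules, %d wanted targets\n",
              length(x$rules), length(x$pattern_rules), length(x$wanted)))
  invisible(x)
}

make_node_rule <- function(node, workdir) {
  inputs <- output_paths(node$upstream, workdir)
  outputs <- intermediate_paths(node, workdir)
  stg <- node$stage
  upstream <- node$upstream
  list(name = paste0(stg$name, ":", sub("\\..*$", "", basename(outputs[1]))),
       outputs = outputs, deps = inputs,
       action = function(ctx) stg$builder(inputs, outputs, upstream, stg, ctx))
}

make_copy_rule <- function(node, workdir) {
  srcs <- output_paths(node$expr, workdir)
  dsts <- node$names
  link <- isTRUE(getOption("typedflow.link_outputs", FALSE))
  list(name = paste0("out:", paste(basename(dsts), collapse = ",")),
       outputs = dsts, deps = srcs,
       action = function(ctx) {
         for (i in seq_along(srcs)) {
           if (file.exists(dsts[i])) unlink(dsts[i])
           dir.create(dirname(dsts[i]), recursive = TRUE, showWarnings = FALSE)
           ok <- if (link) file.symlink(normalizePath(srcs[i]), dsts[i])
                 else file.copy(srcs[i], dsts[i], overwrite = TRUE)
           if (!ok) tf_stop("build", "failed to materialise output '%s'", dsts[i])
         }
         invisible(NULL)
       })
}

#' Compile validated pipelines to build rules
#'
#' Post-order traversal emitting one rule per composed node (outputs are the
#' managed hash-named paths, dependencies the upstream outputs, the action
#' the stage's builder closed over the node). Nodes whose output-path
#' sequence has already been compiled are skipped, so shared prefixes across
#' concurrent workflows compile once. Source nodes emit no rule; explicit
#' [out()] naming appends copy rules. Compiling expressions with outstanding
#' validation errors is refused.
#'
#' @param exprs A pipeline expression or list of them.
#' @param state A [compile_state()] (fresh by default); pass the same state
#'   across calls to deduplicate between them.
#' @param workdir Managed work directory baked into the rules.
#' @return A `tf_ruleset`.
#' @export
compile <- function(exprs, state = compile_state(), workdir = tf_workdir()) {
  if (is_expr(exprs)) exprs <- list(exprs)
  errs <- validation_errors(validate(exprs, workdir))
  if (length(errs)) {
    tf_stop("refuse_compile",
            "refusing to compile: %d validation error(s)\n%s", length(errs),
            paste(vapply(errs, format, ""), collapse = "\n"))
  }
  rs <- new_ruleset()
  emit <- function(rule) {
    key <- paste(rule$outputs, collapse = "\x1f")
    if (!is.null(state$seen[[key]])) return(invisible(NULL))
    assign(key, TRUE, envir = state$seen)
    rs$rules[[length(rs$rules) + 1L]] <<- rule
  }
  go <- function(e) {
    switch(class(e)[1],
      tf_source = invisible(NULL),
      tf_compose = { go(e$upstream); emit(make_node_rule(e, workdir)) },
      tf_allof = { for (p in e$parts) go(p) },
      tf_slice = go(e$parent),
      tf_out = { go(e$expr); emit(make_copy_rule(e, workdir)) }
    )
  }
  for (e in exprs) go(e)
  rs
}

#' Compile pipelines and mark their final outputs as build targets
#'
#' @inheritParams compile
#' @return The `tf_ruleset` with `wanted` set to the final output paths of
#'   every expression.
#' @export
compile_and_want <- function(exprs, state = compile_state(),
                             workdir = tf_workdir()) {
  if (is_expr(exprs)) exprs <- list(exprs)
  rs <- compile(exprs, state = state, workdir = workdir)
  rs$wanted <- unique(unlist(lapply(exprs, output_paths, workdir = workdir)))
  rs
}
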