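# Combinators: explicit output naming, scatter--gather, and the two-phase
# idiom for dynamic workflows.

#' Name the final outputs of a pipeline
#'
#' Managed intermediates carry hash names; only desired outputs need
#' explicit names. `out()` appends copy rules from the managed paths to the
#' given names (symlinks instead with `options(typedflow.link_outputs =
#' TRUE)`); effective tags are unchanged.
#'
#' @param expr A pipeline expression.
#' @param names Character vector of user-visible paths, one per output of
#'   `expr`.
#' @return A pipeline expression whose output paths are `names`.
#' @export
out <- function(expr, names) {
  stopifnot(is_expr(expr))
  k <- length(expr_relpaths(expr))
  if (length(names) != k)
    tf_stop("construction",
            "out(): %d name(s) given for an expression with %d output(s)",
            length(names), k)
  structure(list(expr = expr, names = as.character(names)),
            class = c("tf_out", "tf_expr"))
}

#' Split a multi-output node into single-output expressions
#'
#' The scatter half of scatter--gather: returns one expression per output
#' path, each carrying the parent's effective tags, so further stages
#' compose onto each shard independently. Shard order is the parent's
#' output-path order, making downstream gathering deterministic.
#'
#' @param expr A pipeline expression with arity >= 1.
#' @return List of single-path pipeline expressions.
#' @export
split_outputs <- function(expr) {
  stopifnot(is_expr(expr))
  k <- length(expr_relpaths(expr))
  lapply(seq_len(k), function(i) {
    structure(list(parent = expr, index = i),
              class = c("tf_slice", "tf_expr"))
  })
}

#' Bundle expressions into one multi-path input
#'
#' The gather half (the inverse of [split_outputs()] on paths and tags): a
#' stage composed after the bundle receives the concatenated path list as
#' inputs. The bundle's tags are the intersection of the members' tag sets
#' -- it guarantees only what every member guarantees.
#'
#' @param parts Non-empty list of pipeline expressions.
#' @return An AllOf pipeline expression.
#' @export
with_all <- function(parts) {
  if (is_expr(parts)) parts <- list(parts)
  if (!length(parts))
    tf_stop("construction", "with_all() needs at least one expression")
  stopifnot(all(vapply(parts, is_expr, TRUE)))
  structure(list(parts = parts), class = c("tf_allof", "tf_expr"))
}

#' Validate, compile and build in one call
#'
#' The convenience entry point: runs [validate()] (erroring with the full
#' diagnostic list on failure), [compile_and_want()], then [build()].
#' Callable repeatedly within a session against the same database, which is
#' how dynamic workflows are expressed: run phase one, inspect its outputs
#' (e.g. count assembled contigs), construct phase two, run it.
#'
#' @param exprs A pipeline expression or list of them.
#' @param workdir Managed work directory.
#' @param state Optional [compile_state()] shared across calls.
#' @param ... Passed to [build()] (`jobs`, `db_path`, `executor`,
#'   `keep_going`, `verbose`).
#' @return The [build()] report.
#' @export
execute_workflow <- function(exprs, workdir = tf_workdir(),
                             state = compile_state(), ...) {
  if (is_expr(exprs)) exprs <- list(exprs)
  errs <- validation_errors(validate(exprs, workdir))
  if (length(errs))
    tf_stop("validation", "workflow failed validation (%d error(s)):\n%s",
            length(errs), paste(vapply(errs, format, ""), collapse = "\n"))
  rs <- compile_and_want(exprs, state = state, workdir = workdir)
  build(rs, workdir = workdir, ...)
}
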