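# Stages: named units of computation with tag signatures. define_stage() is
# the boilerplate-reducing factory: given a tag signature and a builder it
# returns a parameterisable constructor, so a stage definition is one call.

#' Construct a stage
#'
#' Usually called through a constructor made by [define_stage()].
#'
#' @param name Stage name; non-empty, filesystem-safe (letters, digits,
#'   `_`, `-`).
#' @param required_tags Tags that must all hold on the upstream expression.
#' @param output_tags Ordered tags asserted for the outputs; the first one
#'   determines the output file extension.
#' @param transient_tags Tags preserved from input to output when present
#'   (e.g. sortedness through a stage that keeps record order).
#' @param builder Function `(inputs, outputs, upstream, stage, ctx)` that
#'   produces the outputs from the inputs; `ctx` gives access to the
#'   executor ([run_command()]) and dynamic dependencies (`ctx$need`).
#' @param params Named list of semantic parameters (folded into the naming
#'   digest).
#' @param n_outputs Number of output files (default 1).
#' @param threads,resources Scheduling hints passed to the executor;
#'   excluded from the naming digest (changing parallelism must not
#'   invalidate outputs).
#' @param values Named list of valued-tag settings introduced by this stage.
#' @return A `tf_stage`.
#' @export
stage <- function(name, required_tags = character(), output_tags,
                  transient_tags = character(), builder,
                  params = list(), n_outputs = 1L, threads = 1L,
                  resources = list(), values = list()) {
  if (!is_string(name) || !nzchar(name) || grepl("[^A-Za-z0-9_-]", name))
    tf_stop("construction", "stage name must be non-empty and filesystem-safe: %s", name)
  if (!length(output_tags))
    tf_stop("construction", "stage '%s' must declare at least one output tag", name)
  n_outputs <- as.integer(n_outputs)
  if (is.na(n_outputs) || n_outputs < 1L)
    tf_stop("construction", "stage '%s': n_outputs must be >= 1", name)
  stopifnot(is.function(builder))
  structure(
    list(name = name,
         params = params,
         required_tags = unique(as.character(required_tags)),
         output_tags = as.character(output_tags),
         transient_tags = unique(as.character(transient_tags)),
         n_outputs = n_outputs,
         threads = max(1L, as.integer(threads)),
         resources = resources,
         builder = builder,
         values = values),
    class = "tf_stage"
  )
}

#' Define a stage constructor
#'
#' The factory that removes per-stage boilerplate: fixes the tag signature
#' and builder once and returns a constructor taking only per-use settings
#' (semantic params, threads, resources). Constructed stages get hash
#' naming, tag bookkeeping and builder wiring automatically.
#'
#' @param algebra The [tag_algebra()] the signature is checked against; the
#'   first output tag must carry a registered file extension.
#' @param name Stage name.
#' @inheritParams stage
#' @param defaults Default semantic parameters, overridable per construction.
#' @param n_outputs Either a fixed integer or the name of a parameter whose
#'   value sets the output arity at construction time (e.g. a sharding
#'   stage's chunk count).
#' @return A constructor `function(..., threads, resources, values)`
#'   returning a `tf_stage`; `...` override `defaults`.
#' @export
define_stage <- function(algebra, name, required_tags = character(),
                         output_tags, transient_tags = character(),
                         builder, defaults = list(), n_outputs = 1L,
                         values = list()) {
  stopifnot(inherits(algebra, "tf_algebra"))
  if (!length(output_tags))
    tf_stop("definition", "stage '%s' must declare at least one output tag", name)
  for (t in unique(c(required_tags, output_tags, transient_tags))) {
    if (!has_tag(algebra, t))
      tf_stop("unknown_tag", "stage '%s' references undeclared tag '%s'", name, t)
  }
  if (is.null(tag_extension(algebra, output_tags[[1]])))
    tf_stop("definition",
            "stage '%s': first output tag '%s' has no registered file extension",
            name, output_tags[[1]])
  force(builder)
  function(..., threads = 1L, resources = list(), values2 = list()) {
    params <- utils::modifyList(defaults, list(...))
    k <- if (is.character(n_outputs)) {
      as.integer(params[[n_outputs]] %||%
                   tf_stop("construction", "stage '%s' needs parameter '%s' for its output arity",
                           name, n_outputs))
    } else as.integer(n_outputs)
    stage(name, params = params, required_tags = required_tags,
          output_tags = output_tags, transient_tags = transient_tags,
          builder = builder, n_outputs = k, threads = threads,
          resources = resources, values = utils::modifyList(values, values2))
  }
}

#' @export
print.tf_stage <- function(x, ...) {
  cat(sprintf("<stage %s> requires {%s} -> outputs [%s]%s\n", x$name,
              paste(x$required_tags, collapse = ", "),
              paste(x$output_tags, collapse = ", "),
              if (x$n_outputs > 1L) sprintf(" x%d", x$n_outputs) else ""))
  invisible(x)
}
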