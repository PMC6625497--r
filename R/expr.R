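# The workflow algebra. A pipeline expression is one of:
#   Source  -- user-named input files plus their declared tags,
#   Compose -- an upstream expression piped into a stage,
#   AllOf   -- a bundle of expressions treated as one multi-path input,
# plus two thin wrappers: Slice (one output of a multi-output node, from
# split()) and Out (explicit naming of final outputs, from out()).
# Construction is total: tag mismatches are reported by validate(), not at
# composition time, mirroring the write-then-compile separation.

#' Create a pipeline source
#'
#' The root of every pipeline: a set of existing input files together with
#' the tags the user asserts for them. Valued tags (e.g. a reference genome
#' association) are passed as named elements of `tags`.
#'
#' @param paths Non-empty character vector of input file paths.
#' @param tags Character vector of declared tag ids; named elements supply
#'   values for valued tags, e.g. `c("ToyFasta", Referenced = "ref.fa")`.
#' @param algebra The [tag_algebra()] the pipeline is checked against.
#' @return A `tf_source` pipeline expression.
#' @export
flow_source <- function(paths, tags = character(), algebra) {
  if (!length(paths) || !is.character(paths) || any(!nzchar(paths)))
    tf_stop("construction", "a source needs at least one non-empty input path")
  stopifnot(inherits(algebra, "tf_algebra"))
  tags <- as.character2(tags)
  values <- as.list(tags$values)
  ids <- tags$ids
  unknown <- setdiff(ids, names(algebra$tags))
  if (length(unknown))
    tf_stop("unknown_tag", "undeclared tag(s) at source: %s",
            paste(unknown, collapse = ", "))
  bad <- setdiff(names(values), valued_tags(algebra))
  if (length(bad))
    tf_stop("construction", "value supplied for non-valued tag(s): %s",
            paste(bad, collapse = ", "))
  structure(
    list(paths = as.character(paths), tags = ids, values = values,
         algebra = algebra),
    class = c("tf_source", "tf_expr")
  )
}

# split a possibly-named tag vector into ids + value map
as.character2 <- function(tags) {
  tags <- unlist(tags) %||% character()
  nms <- names(tags) %||% rep("", length(tags))
  valued <- nzchar(nms)
  list(ids = unique(c(tags[!valued], nms[valued])),
       values = if (any(valued)) as.list(stats::setNames(tags[valued], nms[valued])) else list())
}

#' Compose a stage after a pipeline expression
#'
#' Forward composition: `compose(e, s)` (or `e %>>% s`) feeds the outputs of
#' `e` into stage `s`. Chaining is left-associative, so `a %>>% b %>>% c`
#' groups as `(a %>>% b) %>>% c`. No checking happens here: [validate()] is
#' the single gate.
#'
#' @param upstream A pipeline expression.
#' @param stage A `tf_stage` (or a zero-argument stage constructor).
#' @return A `tf_compose` pipeline expression.
#' @export
compose <- function(upstream, stage) {
  stopifnot(inherits(upstream, "tf_expr"))
  if (is.function(stage)) stage <- stage()
  stopifnot(inherits(stage, "tf_stage"))
  structure(list(upstream = upstream, stage = stage),
            class = c("tf_compose", "tf_expr"))
}

#' @rdname compose
#' @export
`%>>%` <- compose

is_expr <- function(x) inherits(x, "tf_expr")

# The algebra is carried by sources; every expression reaches one.
expr_algebra <- function(expr) {
  switch(class(expr)[1],
    tf_source  = expr$algebra,
    tf_compose = expr_algebra(expr$upstream),
    tf_allof   = expr_algebra(expr$parts[[1]]),
    tf_slice   = expr_algebra(expr$parent),
    tf_out     = expr_algebra(expr$expr),
    tf_stop("internal", "not a pipeline expression: %s", class(expr)[1])
  )
}

# Work-directory-independent names (used for digesting and as path suffixes).
expr_relpaths <- function(expr) {
  switch(class(expr)[1],
    tf_source  = expr$paths,
    tf_compose = node_relnames(expr),
    tf_allof   = unlist(lapply(expr$parts, expr_relpaths)),
    tf_slice   = expr_relpaths(expr$parent)[expr$index],
    tf_out     = expr$names,
    tf_stop("internal", "not a pipeline expression")
  )
}

#' Output paths of a pipeline expression
#'
#' Sources keep their literal paths; composed nodes get managed content-hash
#' names under the work directory; bundles concatenate their parts' paths in
#' order; named outputs report their user-visible names. Pure and
#' deterministic.
#'
#' @param expr A pipeline expression.
#' @param workdir Managed work directory.
#' @return Character vector of file paths.
#' @export
output_paths <- function(expr, workdir = tf_workdir()) {
  switch(class(expr)[1],
    tf_source  = expr$paths,
    tf_compose = intermediate_paths(expr, workdir),
    tf_allof   = unlist(lapply(expr$parts, output_paths, workdir = workdir)),
    tf_slice   = output_paths(expr$parent, workdir)[expr$index],
    tf_out     = expr$names,
    tf_stop("internal", "not a pipeline expression")
  )
}

#' Effective tags of a pipeline expression
#'
#' Sources close their declared tags under the algebra's implications. A
#' composed node carries its stage's output tags, every propagating tag held
#' upstream, and any of the stage's transient tags held upstream -- again
#' closed under implication. A bundle guarantees only what every member
#' guarantees (set intersection).
#'
#' @param expr A pipeline expression.
#' @return Sorted character vector of tag ids.
#' @export
effective_tags <- function(expr) {
  algebra <- expr_algebra(expr)
  eff <- function(e) {
    switch(class(e)[1],
      tf_source = close_tags(algebra, e$tags),
      tf_compose = {
        up <- eff(e$upstream)
        s <- e$stage
        keep <- union(intersect(propagating_tags(algebra), up),
                      intersect(s$transient_tags, up))
        close_tags(algebra, union(union(s$output_tags, names(s$values)), keep))
      },
      tf_allof = {
        sets <- lapply(e$parts, eff)
        tf_sort(Reduce(intersect, sets))
      },
      tf_slice = eff(e$parent),
      tf_out = eff(e$expr),
      tf_stop("internal", "not a pipeline expression")
    )
  }
  eff(expr)
}

#' Retrieve the value of a valued tag
#'
#' Walks from the given node back toward the sources and returns the
#' nearest-upstream value set for the tag (values survive arbitrarily many
#' compositions). Inside a bundle all members must agree.
#'
#' @param expr A pipeline expression (typically the upstream expression a
#'   builder receives).
#' @param id Valued tag identifier.
#' @return The value (text).
#' @export
get_valued <- function(expr, id) {
  v <- find_valued(expr, id)
  if (is.null(v))
    tf_stop("absent_value", "valued tag '%s' is not set anywhere upstream of [%s]",
            id, paste(stage_path(expr), collapse = " -> "))
  v
}

find_valued <- function(expr, id) {
  switch(class(expr)[1],
    tf_source = expr$values[[id]],
    tf_compose = expr$stage$values[[id]] %||% find_valued(expr$upstream, id),
    tf_allof = {
      vals <- unique(unlist(lapply(expr$parts, find_valued, id = id)))
      if (length(vals) > 1L)
        tf_stop("value_conflict", "valued tag '%s' has conflicting values in a bundle: %s",
                id, paste(vals, collapse = " vs "))
      if (length(vals)) vals else NULL
    },
    tf_slice = find_valued(expr$parent, id),
    tf_out = find_valued(expr$expr, id),
    NULL
  )
}

#' Stage names from source to a node
#'
#' @param expr A pipeline expression.
#' @return Character vector of stage names (empty for a bare source).
#' @export
stage_path <- function(expr) {
  switch(class(expr)[1],
    tf_source = character(),
    tf_compose = c(stage_path(expr$upstream), expr$stage$name),
    tf_allof = unique(unlist(lapply(expr$parts, stage_path))),
    tf_slice = stage_path(expr$parent),
    tf_out = stage_path(expr$expr),
    character()
  )
}

#' Look up prior build products by tag
#'
#' Builders can refer backwards along the composition chain: starting at the
#' given node and walking toward the sources, returns the output paths of
#' the nearest node whose effective tags contain every tag in `tags`
#' (e.g. a variant annotator fetching the sorted alignments used for
#' calling). An empty `tags` matches the node itself.
#'
#' @param expr A pipeline expression.
#' @param tags Character vector of required tag ids (the predicate).
#' @param workdir Managed work directory.
#' @return Character vector of paths; empty if no upstream node qualifies.
#' @export
upstream_products <- function(expr, tags = character(), workdir = tf_workdir()) {
  if (all(tags %in% effective_tags(expr)))
    return(output_paths(expr, workdir))
  switch(class(expr)[1],
    tf_source = character(),
    tf_compose = upstream_products(expr$upstream, tags, workdir),
    tf_allof = {
      for (p in expr$parts) {
        hit <- upstream_products(p, tags, workdir)
        if (length(hit)) return(hit)
      }
      character()
    },
    tf_slice = upstream_products(expr$parent, tags, workdir),
    tf_out = upstream_products(expr$expr, tags, workdir),
    character()
  )
}

# enumerate Compose nodes in post-order (upstream first), including those
# inside bundles, slices and named-output wrappers; used by validate/compile
walk_nodes <- function(expr, fn) {
  switch(class(expr)[1],
    tf_source = invisible(NULL),
    tf_compose = { walk_nodes(expr$upstream, fn); fn(expr) },
    tf_allof = { for (p in expr$parts) walk_nodes(p, fn); invisible(NULL) },
    tf_slice = walk_nodes(expr$parent, fn),
    tf_out = walk_nodes(expr$expr, fn),
    invisible(NULL)
  )
}

#' @export
print.tf_expr <- function(x, ...) {
  describe <- function(e) {
    switch(class(e)[1],
      tf_source = sprintf("source[%s]", paste(e$paths, collapse = ",")),
      tf_compose = paste(describe(e$upstream), e$stage$name, sep = " -> "),
      tf_allof = sprintf("all_of(%s)",
                         paste(vapply(e$parts, describe, ""), collapse = "; ")),
      tf_slice = sprintf("%s[%d]", describe(e$parent), e$index),
      tf_out = sprintf("%s => %s", describe(e$expr),
                       paste(e$names, collapse = ",")),
      "?"
    )
  }
  cat("<pipeline> ", describe(x), "\n", sep = "")
  cat("  tags: ", paste(effective_tags(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
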