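# Tag algebra: declared tags, implication rules, and the ontology hierarchy.
#
# Tags are declarative properties of a pipeline node's outputs -- either a
# file format ("Is"-style tags carrying a file extension) or metadata such as
# Sorted / DupsMarked. They are checked at the workflow-graph level only,
# never against file contents, so validation costs nothing at run time.

#' Create an empty tag algebra
#'
#' A tag algebra holds the declared tags, the implication rules between them
#' (e.g. deduplicated files count as duplicate-marked), and optionally an
#' attached ontology. Pipelines are validated against the algebra of their
#' source nodes.
#'
#' @return A `tf_algebra` object.
#' @seealso [declare_tag()], [add_implication()], [close_tags()]
#' @export
tag_algebra <- function() {
  structure(
    list(tags = list(), implications = list(), edam = NULL),
    class = "tf_algebra"
  )
}

#' Declare a tag
#'
#' @param algebra A [tag_algebra()].
#' @param id Tag identifier (unique within the algebra).
#' @param extension File extension for format tags, e.g. `"bam"`. The first
#'   output tag of a stage determines the extension of its output files, so
#'   format tags must carry one.
#' @param valued Does the tag carry a value (e.g. a reference genome path)?
#' @param propagating Does the tag automatically propagate to all downstream
#'   outputs once set (e.g. DeDuped, or a reference association)?
#' @return The updated algebra.
#' @export
declare_tag <- function(algebra, id, extension = NULL, valued = FALSE,
                        propagating = FALSE) {
  stopifnot(inherits(algebra, "tf_algebra"), is_string(id))
  if (id %in% names(algebra$tags))
    tf_stop("redeclared_tag", "tag '%s' is already declared", id)
  algebra$tags[[id]] <- list(
    id = id, extension = extension, valued = isTRUE(valued),
    propagating = isTRUE(propagating)
  )
  algebra
}

#' Add an implication rule between tags
#'
#' Any tag set containing `antecedent` is closed to contain `consequent`:
#' e.g. declaring that deduplicated implies duplicate-marked lets a stage
#' requiring marked duplicates accept deduplicated input.
#'
#' @param algebra A [tag_algebra()].
#' @param antecedent,consequent Declared tag identifiers.
#' @return The updated algebra.
#' @export
add_implication <- function(algebra, antecedent, consequent) {
  stopifnot(inherits(algebra, "tf_algebra"))
  for (id in c(antecedent, consequent)) {
    if (!id %in% names(algebra$tags))
      tf_stop("unknown_tag", "tag '%s' is not declared in the algebra", id)
  }
  algebra$implications[[length(algebra$implications) + 1L]] <-
    c(antecedent, consequent)
  algebra
}

#' Close a tag set under the algebra's implication rules
#'
#' Computes the least fixpoint of the implication relation (which includes
#' any ontology ancestor edges installed by [attach_edam()]). The result is
#' a closure operator: extensive, monotone and idempotent.
#'
#' @param algebra A [tag_algebra()].
#' @param tags Character vector of tag identifiers.
#' @return Sorted character vector containing `tags` and everything implied.
#' @export
close_tags <- function(algebra, tags) {
  stopifnot(inherits(algebra, "tf_algebra"))
  tags <- unique(as.character(tags))
  unknown <- setdiff(tags, names(algebra$tags))
  if (length(unknown))
    tf_stop("unknown_tag", "undeclared tag(s): %s", paste(unknown, collapse = ", "))
  if (!length(algebra$implications)) return(tf_sort(tags))
  ante <- vapply(algebra$implications, `[`, "", 1L)
  cons <- vapply(algebra$implications, `[`, "", 2L)
  out <- tags
  repeat {
    new <- setdiff(cons[ante %in% out], out)
    if (!length(new)) break
    out <- c(out, new)
  }
  tf_sort(out)
}

has_tag <- function(algebra, id) id %in% names(algebra$tags)

tag_extension <- function(algebra, id) {
  t <- algebra$tags[[id]]
  if (is.null(t)) tf_stop("unknown_tag", "tag '%s' is not declared", id)
  t$extension
}

propagating_tags <- function(algebra) {
  ids <- names(algebra$tags)
  ids[vapply(algebra$tags, function(t) t$propagating, logical(1))]
}

valued_tags <- function(algebra) {
  ids <- names(algebra$tags)
  ids[vapply(algebra$tags, function(t) t$valued, logical(1))]
}

#' @export
print.tf_algebra <- function(x, ...) {
  cat("<tf_algebra> ", length(x$tags), " tags, ",
      length(x$implications), " implications",
      if (!is.null(x$edam)) sprintf(", ontology (%d terms)", length(x$edam$terms)),
      "\n", sep = "")
  invisible(x)
}

#' Declare tags and implications from a YAML manifest
#'
#' The manifest has two optional top-level keys: `tags`, a list of entries
#' with fields `id` and optional `extension`, `valued`, `propagating`; and
#' `implications`, a list of two-element `[antecedent, consequent]` pairs.
#'
#' @param path Path to the YAML file.
#' @param algebra Algebra to extend (a fresh one by default).
#' @return The populated algebra.
#' @export
algebra_from_yaml <- function(path, algebra = tag_algebra()) {
  spec <- yaml::read_yaml(path)
  for (t in spec$tags %||% list()) {
    algebra <- declare_tag(algebra, t$id, extension = t$extension,
                           valued = isTRUE(t$valued),
                           propagating = isTRUE(t$propagating))
  }
  for (im in spec$implications %||% list()) {
    algebra <- add_implication(algebra, im[[1]], im[[2]])
  }
  algebra
}
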