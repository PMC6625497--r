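# EDAM ontology support. EDAM organises bioinformatics formats and data
# concepts into an is-a hierarchy; attaching a term to a tag installs
# implications up the ancestor chain, so a stage requiring e.g. the generic
# Fastq format accepts anything tagged with a FASTQ sub-format.

#' Load an ontology from a tabular fixture
#'
#' The file is line-oriented with three tab-separated columns:
#' `term_id<TAB>label<TAB>parent_id[,parent_id...]` (third column empty for
#' roots). Lines starting with `#` and blank lines are ignored. A small
#' subset of the EDAM format/data axes ships with the package under
#' `system.file("extdata", "edam_subset.tsv", package = "typedflow")`.
#'
#' @param path Path to the fixture file.
#' @return A `tf_ontology`: list of terms, each with `label` and `parents`.
#' @export
load_edam <- function(path) {
  if (!file.exists(path)) tf_stop("missing_file", "ontology file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  terms <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      tf_stop("malformed_ontology", "bad ontology record: %s", ln)
    parents <- if (length(f) >= 3L && nzchar(f[3])) {
      strsplit(f[3], ",", fixed = TRUE)[[1]]
    } else character()
    if (f[1] %in% parents)
      tf_stop("malformed_ontology", "term '%s' lists itself as a parent", f[1])
    terms[[f[1]]] <- list(id = f[1], label = f[2], parents = parents)
  }
  onto <- structure(list(terms = terms), class = "tf_ontology")
  check_ontology(onto)
  onto
}

check_ontology <- function(onto) {
  ids <- names(onto$terms)
  for (t in onto$terms) {
    dangling <- setdiff(t$parents, ids)
    if (length(dangling))
      tf_stop("missing_parent", "term '%s' references unknown parent(s): %s",
              t$id, paste(dangling, collapse = ", "))
  }
  # cycle check: repeated ancestor expansion must terminate for every term
  for (id in ids) {
    seen <- character()
    frontier <- id
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(onto$terms[frontier], `[[`, "parents")))
      if (id %in% nxt)
        tf_stop("malformed_ontology", "ontology cycle through term '%s'", id)
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
      frontier <- nxt
    }
  }
  invisible(onto)
}

#' Short tag name for an ontology term
#'
#' Terms are addressed in tag algebras by a CamelCase short name derived from
#' their label, e.g. the FASTQ-illumina format term becomes `FastqIllumina`.
#'
#' @param label Term label text.
#' @return A single identifier string.
#' @export
edam_short_name <- function(label) {
  parts <- strsplit(gsub("[^A-Za-z0-9]+", " ", label), " ", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  paste(vapply(parts, function(p) {
    paste0(toupper(substr(p, 1, 1)), tolower(substr(p, 2, nchar(p))))
  }, ""), collapse = "")
}

ontology_ancestors <- function(onto, term_id) {
  if (!term_id %in% names(onto$terms))
    tf_stop("unknown_term", "term '%s' not in ontology", term_id)
  out <- character()
  frontier <- onto$terms[[term_id]]$parents
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(onto$terms[frontier], `[[`, "parents"))), out)
  }
  tf_sort(out)
}

term_tag_id <- function(onto, term_id) {
  lbl <- onto$terms[[term_id]]$label
  nm <- edam_short_name(lbl)
  if (nzchar(nm)) nm else term_id
}

#' Attach an ontology term to a tag
#'
#' Installs the ontology in the algebra (first call), declares tags for the
#' term and each of its ancestors (by short name), and adds implications
#' `tag_id => term` and `term => parent` along every ancestor edge, so a
#' tagged type matches requirements at any level of the hierarchy.
#'
#' @param algebra A [tag_algebra()].
#' @param tag_id Declared tag to annotate.
#' @param term_id Ontology term identifier (e.g. `"format_1931"`).
#' @param ontology The [load_edam()] ontology; defaults to one already
#'   attached to the algebra.
#' @return The updated algebra.
#' @export
attach_edam <- function(algebra, tag_id, term_id, ontology = algebra$edam) {
  stopifnot(inherits(algebra, "tf_algebra"))
  if (is.null(ontology))
    tf_stop("unknown_term", "no ontology attached to the algebra or supplied")
  if (!has_tag(algebra, tag_id))
    tf_stop("unknown_tag", "tag '%s' is not declared", tag_id)
  if (!term_id %in% names(ontology$terms))
    tf_stop("unknown_term", "term '%s' not in ontology", term_id)
  algebra$edam <- ontology
  ensure_term_tag <- function(alg, tid) {
    nm <- term_tag_id(ontology, tid)
    if (!has_tag(alg, nm)) alg <- declare_tag(alg, nm)
    alg
  }
  # declare the term and all ancestors as tags, then wire is-a implications
  chain <- c(term_id, ontology_ancestors(ontology, term_id))
  for (tid in chain) algebra <- ensure_term_tag(algebra, tid)
  algebra <- add_implication(algebra, tag_id, term_tag_id(ontology, term_id))
  for (tid in chain) {
    for (p in ontology$terms[[tid]]$parents) {
      algebra <- add_implication(algebra, term_tag_id(ontology, tid),
                                 term_tag_id(ontology, p))
    }
  }
  algebra
}
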