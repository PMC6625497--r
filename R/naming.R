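# Content-hash naming of managed intermediates. A node's file names are a
# deterministic function of its upstream paths, stage name and semantic
# parameters -- never of the work directory, thread count or resource
# requests -- so renaming the workspace or changing parallelism cannot
# invalidate existing outputs.

#' Digest used for intermediate file naming
#'
#' SHA-1 over a canonical byte serialisation (length-prefixed input paths,
#' stage name, sorted `key=value` parameters), base32-encoded lowercase.
#' A 20-byte SHA-1 encodes to exactly 32 base32 characters.
#'
#' @param input_paths Character vector of input paths, in pipeline order.
#' @param stage_name Stage name.
#' @param params Named list of scalar parameters (threads and resource
#'   requests are excluded by the caller: they do not affect file content).
#' @return A 32-character lowercase base32 string.
#' @export
tf_digest <- function(input_paths, stage_name, params = list()) {
  enc <- function(s) paste0(nchar(s, type = "bytes"), ":", s)
  keys <- tf_sort(names(params) %||% character())
  kv <- vapply(keys, function(k) paste0(k, "=", format(params[[k]], digits = 15)), "")
  payload <- paste(
    c("paths", vapply(as.character(input_paths), enc, ""),
      "stage", enc(stage_name),
      "params", vapply(kv, enc, "")),
    collapse = "|")
  hex <- digest::digest(payload, algo = "sha1", serialize = FALSE)
  base32_from_hex(hex)
}

# RFC 4648 base32 (lowercase) of a hex string with bit length divisible by 5*8
base32_from_hex <- function(hex) {
  alphabet <- strsplit("abcdefghijklmnopqrstuvwxyz234567", "")[[1]]
  bytes <- strtoi(substring(hex, seq(1, nchar(hex) - 1, 2),
                            seq(2, nchar(hex), 2)), 16L)
  bits <- unlist(lapply(bytes, function(b) as.integer(intToBits(b)[8:1])))
  n <- (length(bits) %/% 5) * 5
  idx <- matrix(bits[seq_len(n)], nrow = 5)
  vals <- as.integer(crossprod(idx, 2L^(4:0)))
  paste(alphabet[vals + 1L], collapse = "")
}

# Work-directory-relative names for a Compose node; digests are computed over
# the *relative* upstream names so the digest chain is location-independent.
node_relnames <- function(node) {
  stage <- node$stage
  dg <- tf_digest(expr_relpaths(node$upstream), stage$name, stage$params)
  ext <- node_extension(node)
  if (stage$n_outputs == 1L) {
    paste0(dg, ".", stage$name, ".", ext)
  } else {
    paste0(dg, ".", stage$name, ".", seq_len(stage$n_outputs), ".", ext)
  }
}

node_extension <- function(node) {
  algebra <- expr_algebra(node)
  first <- node$stage$output_tags[[1]]
  ext <- tag_extension(algebra, first)
  if (is.null(ext))
    tf_stop("naming", "first output tag '%s' of stage '%s' has no registered file extension",
            first, node$stage$name)
  ext
}

#' Managed paths of a composed node
#'
#' `"<workdir>/<digest>.<stage>.<ext>"` for single-output stages, with a
#' 1-based index segment inserted for multi-output stages. The extension is
#' that registered for the stage's first output tag.
#'
#' @param node A Compose node (built by [compose()]).
#' @param workdir Managed work directory (see [tf_workdir()]).
#' @return Character vector of `n_outputs` paths.
#' @export
intermediate_paths <- function(node, workdir = tf_workdir()) {
  stopifnot(inherits(node, "tf_compose"))
  file.path(workdir, node_relnames(node))
}
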