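# Self-contained toy stage pack: a miniature resequencing tool chain
# (aligner, mate fixer, sorter, duplicate marker, variant caller), a
# scatter--gather k-mer search (chunk/blast/extract/concat) and a toy
# assembler. Every builder is a pure text transformation implemented by the
# bundled stand-alone script inst/tools/toytool.R and invoked through
# run_command(), so the executor layer is exercised on every build.
# Builders defensively validate their input dialect and fail loudly on a
# mismatch -- which is exactly what makes the validator's soundness
# guarantee testable.
#
# Text dialects:
#   reference/reads/contigs: standard FASTA;
#   alignments ("tal"): one record per line,
#     read_id<TAB>contig<TAB>pos(1-based)<TAB>flags('.'|'dup')<TAB>sequence;
#   variant calls: minimal VCF dialect (## headers, #CHROM line, 8 columns).

#' The toy tag algebra
#'
#' Format tags: `ToyFasta` (.fa), `ToyBam` (.tal, the toy alignment
#' dialect), `ToyVcf` (.vcf), `ToyTsv` (.tsv), `ToyTxt` (.txt). Metadata
#' tags: `Sorted`, `DupsMarked`, `DeDuped` (propagating), and the valued,
#' propagating `Referenced` tag carrying the reference genome path.
#' One implication: deduplicated files count as duplicate-marked.
#'
#' @return A [tag_algebra()].
#' @export
toy_algebra <- function() {
  a <- tag_algebra()
  a <- declare_tag(a, "ToyFasta", extension = "fa")
  a <- declare_tag(a, "ToyBam", extension = "tal")
  a <- declare_tag(a, "ToyVcf", extension = "vcf")
  a <- declare_tag(a, "ToyTsv", extension = "tsv")
  a <- declare_tag(a, "ToyTxt", extension = "txt")
  a <- declare_tag(a, "Sorted")
  a <- declare_tag(a, "DupsMarked")
  a <- declare_tag(a, "DeDuped", propagating = TRUE)
  a <- declare_tag(a, "Referenced", valued = TRUE, propagating = TRUE)
  add_implication(a, "DeDuped", "DupsMarked")
}

toy_run <- function(ctx, stg, args) {
  run_command(ctx$executor,
              c(rscript_bin(), "--vanilla", toytool_path(), args),
              resources = utils::modifyList(list(threads = stg$threads),
                                            stg$resources),
              id = stg$name)
}

#' The toy stage pack
#'
#' Stage constructors over the given algebra (see [toy_algebra()]):
#' \describe{
#'   \item{align}{exact-match placement of reads on the reference named by
#'     the `Referenced` valued tag; tolerates the odd mismatch so reads
#'     spanning a variant still place. `ToyFasta + Referenced -> ToyBam`.}
#'   \item{fix_mates}{record normalisation pass-through.
#'     `ToyBam -> ToyBam`, preserves `Sorted`/`DupsMarked`.}
#'   \item{sort}{orders records by (contig, position, read id); receives its
#'     thread count as a `-@` token. `ToyBam -> ToyBam + Sorted`.}
#'   \item{mark_dups}{flags records after the first at each (contig,
#'     position). `ToyBam + Sorted -> + DupsMarked`, preserves `Sorted`.}
#'   \item{dedup}{removes them instead. `-> + DeDuped` (propagating;
#'     implies `DupsMarked`).}
#'   \item{call}{pileup caller: positions where at least `min_support`
#'     non-duplicate reads agree on a non-reference base, written in the
#'     minimal VCF dialect. `ToyBam + Sorted + DupsMarked + Referenced ->
#'     ToyVcf`.}
#'   \item{chunk}{round-robin FASTA sharding into `n` files
#'     (`n_outputs = n`).}
#'   \item{toy_blast}{shared k-mer count of each query record against every
#'     subject record (`subject` is a semantic parameter).
#'     `ToyFasta -> ToyTsv`.}
#'   \item{extract}{top `m` hits per query. `ToyTsv -> ToyTsv`.}
#'   \item{assemble}{groups reads by origin into consensus contigs.
#'     `ToyFasta -> ToyFasta`.}
#'   \item{process_contig}{per-contig summary line (id, length, GC).
#'     `ToyFasta -> ToyTxt`.}
#'   \item{concat}{ordered concatenation; with `sort_lines = TRUE` the
#'     gathered lines are also sorted (C locale), making the gather
#'     order-insensitive. `ToyTsv -> ToyTsv`.}
#' }
#'
#' @param algebra A [tag_algebra()] with the toy tags declared.
#' @return Named list of stage constructors (see [define_stage()]).
#' @export
toy_stages <- function(algebra = toy_algebra()) {
  list(
    align = define_stage(
      algebra, "align", c("ToyFasta", "Referenced"), c("ToyBam"),
      builder = function(inputs, outputs, upstream, stg, ctx) {
        ref <- get_valued(upstream, "Referenced")
        ctx$need(ref)
        toy_run(ctx, stg, c("align", ref, outputs[1], inputs))
      }),
    fix_mates = define_stage(
      algebra, "fixmates", "ToyBam", "ToyBam",
      transient_tags = c("Sorted", "DupsMarked", "DeDuped"),
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("fixmates", inputs[1], outputs[1]))
      }),
    sort = define_stage(
      algebra, "sort", "ToyBam", c("ToyBam", "Sorted"),
      transient_tags = c("DupsMarked", "DeDuped"),
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("sort", inputs[1], outputs[1], "-@", stg$threads))
      }),
    mark_dups = define_stage(
      algebra, "markdups", c("ToyBam", "Sorted"), c("ToyBam", "DupsMarked"),
      transient_tags = "Sorted",
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("markdups", inputs[1], outputs[1]))
      }),
    dedup = define_stage(
      algebra, "dedup", c("ToyBam", "Sorted"), c("ToyBam", "DeDuped"),
      transient_tags = "Sorted",
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("dedup", inputs[1], outputs[1]))
      }),
    call = define_stage(
      algebra, "call", c("ToyBam", "Sorted", "DupsMarked", "Referenced"),
      "ToyVcf", defaults = list(min_support = 2L),
      builder = function(inputs, outputs, upstream, stg, ctx) {
        ref <- get_valued(upstream, "Referenced")
        ctx$need(ref)
        toy_run(ctx, stg, c("call", ref, inputs[1], outputs[1],
                            stg$params$min_support))
      }),
    chunk = define_stage(
      algebra, "chunk", "ToyFasta", "ToyFasta",
      defaults = list(n = 2L), n_outputs = "n",
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("chunk", inputs[1], outputs))
      }),
    toy_blast = define_stage(
      algebra, "blast", "ToyFasta", "ToyTsv",
      defaults = list(subject = NULL, k = 8L),
      builder = function(inputs, outputs, upstream, stg, ctx) {
        subject <- stg$params$subject
        if (is.null(subject))
          tf_stop("construction", "toy_blast needs a 'subject' parameter")
        ctx$need(subject)
        toy_run(ctx, stg, c("blast", subject, inputs[1], outputs[1],
                            stg$params$k))
      }),
    extract = define_stage(
      algebra, "extract", "ToyTsv", "ToyTsv", defaults = list(m = 3L),
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("extract", inputs[1], outputs[1], stg$params$m))
      }),
    assemble = define_stage(
      algebra, "assemble", "ToyFasta", "ToyFasta",
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("assemble", outputs[1], inputs))
      }),
    process_contig = define_stage(
      algebra, "processcontig", "ToyFasta", "ToyTxt",
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("process_contig", inputs[1], outputs[1]))
      }),
    concat = define_stage(
      algebra, "concat", "ToyTsv", "ToyTsv",
      defaults = list(sort_lines = TRUE),
      builder = function(inputs, outputs, upstream, stg, ctx) {
        toy_run(ctx, stg, c("concat",
                            if (isTRUE(stg$params$sort_lines)) "sorted" else "plain",
                            outputs[1], inputs))
      })
  )
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

write_fasta <- function(ids, seqs, path) {
  write_lines_atomic(as.vector(rbind(paste0(">", ids), seqs)), path)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic resequencing data set
#'
#' Writes a reference (`ref.fa`) of random contigs and a read set
#' (`reads.fa`) sampled from a mutated copy of the reference, plus
#' plain-text truth tables. Point variants are planted at positions spaced
#' at least a read length apart; each variant receives three supporting
#' reads at distinct offsets, so a correct align/sort/mark-duplicates/call
#' chain recovers the planted variants exactly (reads carry no sequencing
#' error, so there are no spurious calls). A fraction of reads is
#' duplicated in place to exercise duplicate marking. Read ids record their
#' origin (`r<i>_<contig>_<start>`), which is the ground truth used by
#' oracle checks and by the toy assembler. Deterministic for a given seed.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @param n_reads Total number of reads, duplicates included.
#' @param n_contigs Number of reference contigs.
#' @param contig_len Contig length (bases).
#' @param read_len Read length (bases); must be < `contig_len` / 2.
#' @param dup_fraction Fraction of reads that are in-place duplicates.
#' @param variants_per_contig Planted point variants per contig.
#' @return List with file paths (`ref`, `reads`, `variants_tsv`), the truth
#'   tables (`variants`, `reads_table` data frames), and the expected
#'   duplicate-flag count `n_duplicate_records`.
#' @export
gen_reads <- function(dir, seed = 1L, n_reads = 200L, n_contigs = 5L,
                      contig_len = 600L, read_len = 60L,
                      dup_fraction = 0.1, variants_per_contig = 2L) {
  stopifnot(n_reads > 0, n_contigs > 0, read_len > 0,
            contig_len > 2L * read_len + 4L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    contig_ids <- sprintf("c%d", seq_len(n_contigs))
    ref <- stats::setNames(vapply(contig_ids, function(i) random_dna(contig_len), ""),
                           contig_ids)

    # plant variants: positions spaced >= read_len + 10 so any read spans at
    # most one, keeping the toy aligner's mismatch tolerance trivial
    lo <- read_len + 1L
    hi <- contig_len - read_len - 1L
    vars <- do.call(rbind, lapply(contig_ids, function(cid) {
      pos <- integer()
      cand <- sample(seq(lo, hi))
      for (p in cand) {
        if (length(pos) >= variants_per_contig) break
        if (!length(pos) || all(abs(pos - p) >= read_len + 10L)) pos <- c(pos, p)
      }
      pos <- sort(pos)
      refb <- substring(ref[[cid]], pos, pos)
      altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      data.frame(contig = cid, pos = pos, ref = refb, alt = altb,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))

    mutated <- ref
    for (i in seq_len(nrow(vars))) {
      cid <- vars$contig[i]
      substr(mutated[[cid]], vars$pos[i], vars$pos[i]) <- vars$alt[i]
    }

    # guaranteed variant support: three reads at distinct offsets per variant
    support <- do.call(rbind, lapply(seq_len(nrow(vars)), function(i) {
      data.frame(contig = vars$contig[i],
                 start = vars$pos[i] - c(10L, 25L, 40L),
                 stringsAsFactors = FALSE)
    }))
    n_dup <- round(n_reads * dup_fraction)
    n_random <- n_reads - n_dup - nrow(support)
    if (n_random < 0)
      tf_stop("construction", "n_reads too small for %d planted variants", nrow(vars))
    rand <- data.frame(
      contig = sample(contig_ids, n_random, replace = TRUE),
      start = sample.int(contig_len - read_len + 1L, n_random, replace = TRUE),
      stringsAsFactors = FALSE)
    base <- rbind(support, rand)
    base$seq <- vapply(seq_len(nrow(base)), function(i) {
      substring(mutated[[base$contig[i]]], base$start[i],
                base$start[i] + read_len - 1L)
    }, "")
    base$id <- sprintf("r%d_%s_%d", seq_len(nrow(base)), base$contig, base$start)

    dups <- base[sample.int(nrow(base), n_dup, replace = TRUE), , drop = FALSE]
    if (nrow(dups)) dups$id <- sprintf("d%d_%s_%d", seq_len(nrow(dups)),
                                       dups$contig, dups$start)
    reads <- rbind(base, dups)

    # expected duplicate-flag count under the positional toy definition:
    # every record after the first at each (contig, start)
    n_dup_records <- nrow(reads) -
      nrow(unique(reads[, c("contig", "start")]))

    ref_path <- file.path(dir, "ref.fa")
    reads_path <- file.path(dir, "reads.fa")
    vars_path <- file.path(dir, "truth_variants.tsv")
    write_fasta(contig_ids, unname(ref), ref_path)
    write_fasta(reads$id, reads$seq, reads_path)
    utils::write.table(vars, vars_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(ref = ref_path, reads = reads_path, variants_tsv = vars_path,
         variants = vars, reads_table = reads,
         n_duplicate_records = n_dup_records)
  })
}

#' Sample a random toy pipeline
#'
#' Draws a chain of 1 to `max_len` stages (uniformly, with replacement)
#' from the linear resequencing pack -- align, fix_mates, sort, mark_dups,
#' dedup, call -- and composes it after `src`. Used to probe the
#' validator's soundness guarantee: most sampled orderings are mis-tagged
#' and must be rejected by [validate()], while every chain that passes must
#' execute without any in-builder dialect failure. Uses the current RNG
#' state; seed outside for reproducibility.
#'
#' @param src Source expression (a reads FASTA with the `Referenced` value
#'   set, as produced from [gen_reads()] output).
#' @param stages The [toy_stages()] constructor list.
#' @param max_len Maximum chain length.
#' @return A pipeline expression.
#' @export
sample_toy_pipeline <- function(src, stages, max_len = 5L) {
  pool <- c("align", "fix_mates", "sort", "mark_dups", "dedup", "call")
  chain <- sample(pool, sample.int(max_len, 1L), replace = TRUE)
  e <- src
  for (nm in chain) e <- compose(e, stages[[nm]]())
  e
}
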