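#!/usr/bin/env Rscript
# Stand-alone toy bioinformatics tool chain used by the typedflow toy stage
# pack. Deliberately dependency-free (base R only, instant startup) and
# strict about its input dialects: every subcommand validates its inputs and
# exits non-zero with a clear message on any mismatch, so running a stage on
# the wrong file type fails loudly rather than silently producing nonsense.
#
# Dialects:
#   FASTA: standard, sequences on one or more lines.
#   tal (toy alignment): tab-separated, one record per line:
#        read_id  contig  pos(1-based)  flags('.'|'dup')  sequence
#   vcf (toy variant calls): "##" headers, "#CHROM" column line, 8 columns.

die <- function(fmt, ...) {
  cat(sprintf(paste0("toytool: ", fmt, "\n"), ...), file = stderr())
  quit(save = "no", status = 1L)
}

read_fasta <- function(path) {
  if (!file.exists(path)) die("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1], ">"))
    die("%s is not FASTA (expected '>' on the first line)", path)
  hdr <- grepl("^>", lines)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(seq_along(id), function(i) {
    paste(lines[!hdr & grp == i], collapse = "")
  }, "")
  if (any(grepl("[^ACGTNacgtn]", seqs)))
    die("%s contains non-nucleotide characters", path)
  list(id = id, seq = toupper(seqs))
}

write_fasta <- function(fa, path) {
  writeLines(as.vector(rbind(paste0(">", fa$id), fa$seq)), path)
}

read_tal <- function(path) {
  if (!file.exists(path)) die("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && any(startsWith(lines, ">")))
    die("%s looks like FASTA, not the tal alignment dialect", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    die("%s is not in the tal alignment dialect (need 5 tab-separated fields)", path)
  df <- data.frame(
    id = vapply(parts, `[`, "", 1L),
    contig = vapply(parts, `[`, "", 2L),
    pos = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    flags = vapply(parts, `[`, "", 4L),
    seq = vapply(parts, `[`, "", 5L),
    stringsAsFactors = FALSE)
  if (nrow(df) && (anyNA(df$pos) || any(!df$flags %in% c(".", "dup"))))
    die("%s has malformed tal records", path)
  df
}

write_tal <- function(df, path) {
  writeLines(sprintf("%s\t%s\t%d\t%s\t%s",
                     df$id, df$contig, df$pos, df$flags, df$seq), path)
}

tal_sorted <- function(df) {
  if (nrow(df) < 2L) return(TRUE)
  o <- order(df$contig, df$pos, df$id, method = "radix")
  identical(o, seq_len(nrow(df)))
}

require_sorted <- function(df, path) {
  if (!tal_sorted(df)) die("%s is not coordinate-sorted", path)
}

count_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# ---- subcommands -----------------------------------------------------------

cmd_align <- function(args) {
  if (length(args) < 3L) die("usage: align ref.fa out.tal reads.fa...")
  ref <- read_fasta(args[1])
  outp <- args[2]
  recs <- list()
  for (rf in args[-(1:2)]) {
    reads <- read_fasta(rf)
    for (i in seq_along(reads$id)) {
      sq <- reads$seq[i]
      L <- nchar(sq)
      half <- max(1L, L %/% 2L)
      seeds <- c(substr(sq, 1L, half), substr(sq, half + 1L, L))
      offs <- c(0L, half)
      best <- NULL
      for (ci in seq_along(ref$id)) {
        contig <- ref$seq[ci]
        for (k in 1:2) {
          hits <- gregexpr(seeds[k], contig, fixed = TRUE)[[1]]
          if (hits[1] == -1L) next
          for (h in hits) {
            start <- h - offs[k]
            if (start < 1L || start + L - 1L > nchar(contig)) next
            mm <- count_mismatches(sq, substr(contig, start, start + L - 1L))
            if (mm <= 3L) {
              cand <- list(contig = ref$id[ci], pos = start, mm = mm)
              if (is.null(best) || cand$mm < best$mm) best <- cand
            }
          }
        }
        if (!is.null(best) && best$mm == 0L) break
      }
      if (!is.null(best)) {
        recs[[length(recs) + 1L]] <- data.frame(
          id = reads$id[i], contig = best$contig, pos = best$pos,
          flags = ".", seq = sq, stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = character(), contig = character(), pos = integer(),
               flags = character(), seq = character())
  write_tal(df, outp)
}

cmd_fixmates <- function(args) {
  if (length(args) != 2L) die("usage: fixmates in.tal out.tal")
  write_tal(read_tal(args[1]), args[2])
}

cmd_sort <- function(args) {
  if (length(args) < 2L) die("usage: sort in.tal out.tal [-@ n]")
  df <- read_tal(args[1])
  df <- df[order(df$contig, df$pos, df$id, method = "radix"), , drop = FALSE]
  write_tal(df, args[2])
}

cmd_markdups <- function(args, drop = FALSE) {
  if (length(args) != 2L) die("usage: markdups|dedup in.tal out.tal")
  df <- read_tal(args[1])
  require_sorted(df, args[1])
  dup <- duplicated(df[, c("contig", "pos")])
  if (drop) {
    df <- df[!dup, , drop = FALSE]
  } else {
    df$flags[dup] <- "dup"
  }
  write_tal(df, args[2])
}

cmd_call <- function(args) {
  if (length(args) < 3L) die("usage: call ref.fa in.tal out.vcf [min_support]")
  ref <- read_fasta(args[1])
  df <- read_tal(args[2])
  min_support <- if (length(args) >= 4L) as.integer(args[4]) else 2L
  require_sorted(df, args[2])
  df <- df[df$flags != "dup", , drop = FALSE]
  refseq <- setNames(ref$seq, ref$id)
  tall <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df))) {
    cid <- df$contig[i]
    if (is.na(refseq[cid])) die("alignment contig '%s' absent from reference", cid)
    rs <- refseq[[cid]]
    sq <- df$seq[i]
    p0 <- df$pos[i]
    rb <- utf8ToInt(substr(rs, p0, p0 + nchar(sq) - 1L))
    qb <- utf8ToInt(sq)
    mis <- which(qb != rb)
    for (m in mis) {
      key <- sprintf("%s\t%d\t%s", cid, p0 + m - 1L, intToUtf8(qb[m]))
      tall[[key]] <- (tall[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(tall)
  rows <- character()
  if (length(keys)) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    tab <- data.frame(contig = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      alt = vapply(parts, `[`, "", 3L),
                      n = vapply(keys, function(k) tall[[k]], 0L),
                      stringsAsFactors = FALSE)
    tab <- tab[tab$n >= min_support, , drop = FALSE]
    tab <- tab[order(tab$contig, tab$pos, tab$alt, method = "radix"), , drop = FALSE]
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d",
                    tab$contig, tab$pos,
                    substr(refseq[tab$contig], tab$pos, tab$pos),
                    tab$alt, tab$n)
  }
  writeLines(c("##fileformat=VCFv4.2",
               "##source=typedflow-toytool",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), args[3])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

cmd_chunk <- function(args) {
  if (length(args) < 2L) die("usage: chunk in.fa out1.fa [out2.fa ...]")
  fa <- read_fasta(args[1])
  outs <- args[-1]
  n <- length(outs)
  for (j in seq_len(n)) {
    sel <- which(((seq_along(fa$id) - 1L) %% n) + 1L == j)
    write_fasta(list(id = fa$id[sel], seq = fa$seq[sel]), outs[j])
  }
}

kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character())
  unique(substring(s, 1:(L - k + 1L), k:L))
}

cmd_blast <- function(args) {
  if (length(args) < 3L) die("usage: blast subject.fa query.fa out.tsv [k]")
  subject <- read_fasta(args[1])
  query <- read_fasta(args[2])
  k <- if (length(args) >= 4L) as.integer(args[4]) else 8L
  skmers <- lapply(subject$seq, kmers, k = k)
  lines <- character()
  for (i in seq_along(query$id)) {
    qk <- kmers(query$seq[i], k)
    sc <- vapply(skmers, function(s) length(intersect(qk, s)), 0L)
    lines <- c(lines, sprintf("%s\t%s\t%d", query$id[i], subject$id, sc))
  }
  writeLines(lines, args[3])
}

read_tsv3 <- function(path) {
  if (!file.exists(path)) die("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    die("%s is not a query/subject/score tsv", path)
  data.frame(query = vapply(parts, `[`, "", 1L),
             subject = vapply(parts, `[`, "", 2L),
             score = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
             stringsAsFactors = FALSE)
}

cmd_extract <- function(args) {
  if (length(args) < 2L) die("usage: extract in.tsv out.tsv [m]")
  df <- read_tsv3(args[1])
  if (anyNA(df$score)) die("%s has non-integer scores", args[1])
  m <- if (length(args) >= 3L) as.integer(args[3]) else 3L
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$query), function(ix) {
    o <- ix[order(-df$score[ix], df$subject[ix], method = "radix")]
    utils::head(o, m)
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%d", df$query, df$subject, df$score), args[2])
}

cmd_assemble <- function(args) {
  if (length(args) < 2L) die("usage: assemble out.fa reads.fa...")
  outp <- args[1]
  ids <- character(); seqs <- character(); starts <- integer(); origin <- character()
  for (rf in args[-1]) {
    fa <- read_fasta(rf)
    m <- regmatches(fa$id, regexec("^[rd][0-9]+_(c[0-9]+)_([0-9]+)$", fa$id))
    bad <- which(lengths(m) != 3L)
    if (length(bad))
      die("%s: read id '%s' carries no origin; cannot toy-assemble",
          rf, fa$id[bad[1]])
    ids <- c(ids, fa$id); seqs <- c(seqs, fa$seq)
    origin <- c(origin, vapply(m, `[`, "", 2L))
    starts <- c(starts, as.integer(vapply(m, `[`, "", 3L)))
  }
  contigs <- sort(unique(origin))
  asm_id <- character(); asm_seq <- character()
  for (cid in contigs) {
    sel <- which(origin == cid)
    span <- max(starts[sel] + nchar(seqs[sel]) - 1L)
    cons <- rep(NA_character_, span)
    for (i in sel[order(starts[sel], ids[sel], method = "radix")]) {
      b <- strsplit(seqs[i], "")[[1]]
      at <- starts[i] + seq_along(b) - 1L
      put <- is.na(cons[at])
      cons[at[put]] <- b[put]
    }
    covered <- which(!is.na(cons))
    asm_id <- c(asm_id, cid)
    asm_seq <- c(asm_seq, paste(ifelse(is.na(cons), "N", cons)[
      min(covered):max(covered)], collapse = ""))
  }
  write_fasta(list(id = asm_id, seq = asm_seq), outp)
}

cmd_process_contig <- function(args) {
  if (length(args) != 2L) die("usage: process_contig in.fa out.txt")
  fa <- read_fasta(args[1])
  gc <- vapply(fa$seq, function(s) {
    b <- utf8ToInt(s)
    round(sum(b == utf8ToInt("G") | b == utf8ToInt("C")) / length(b), 4)
  }, 0)
  writeLines(sprintf("%s\t%d\t%.4f", fa$id, nchar(fa$seq), gc), args[2])
}

cmd_concat <- function(args) {
  if (length(args) < 3L) die("usage: concat sorted|plain out.tsv in1 [in2 ...]")
  mode <- args[1]
  if (!mode %in% c("sorted", "plain")) die("concat mode must be 'sorted' or 'plain'")
  lines <- unlist(lapply(args[-(1:2)], function(p) {
    read_tsv3(p)  # dialect check only
    l <- readLines(p, warn = FALSE)
    l[nzchar(l)]
  }))
  if (mode == "sorted") lines <- sort(lines, method = "radix")
  writeLines(lines, args[2])
}

main <- function() {
  argv <- commandArgs(trailingOnly = TRUE)
  if (!length(argv)) die("usage: toytool.R <subcommand> ...")
  cmd <- argv[1]; args <- argv[-1]
  switch(cmd,
         align = cmd_align(args),
         fixmates = cmd_fixmates(args),
         sort = cmd_sort(args),
         markdups = cmd_markdups(args, drop = FALSE),
         dedup = cmd_markdups(args, drop = TRUE),
         call = cmd_call(args),
         chunk = cmd_chunk(args),
         blast = cmd_blast(args),
         extract = cmd_extract(args),
         assemble = cmd_assemble(args),
         process_contig = cmd_process_contig(args),
         concat = cmd_concat(args),
         die("unknown subcommand '%s'", cmd))
  invisible(NULL)
}

main()
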