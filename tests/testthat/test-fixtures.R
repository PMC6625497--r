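test_that("the read generator is byte-deterministic for a seed", {
  dir <- local_workspace()
  g1 <- gen_reads(file.path(dir, "one"), seed = 13, n_reads = 60)
  g2 <- gen_reads(file.path(dir, "two"), seed = 13, n_reads = 60)
  expect_identical(readLines(g1$ref), readLines(g2$ref))
  expect_identical(readLines(g1$reads), readLines(g2$reads))
  g3 <- gen_reads(file.path(dir, "three"), seed = 14, n_reads = 60)
  expect_false(identical(readLines(g1$reads), readLines(g3$reads)))
})

test_that("the reference has one record per contig and reads honour sizes", {
  local_workspace()
  g <- gen_reads("d", seed = 2, n_reads = 50, n_contigs = 5, read_len = 40,
                 contig_len = 300)
  ref <- readLines(g$ref)
  expect_identical(sum(startsWith(ref, ">")), 5L)
  reads <- readLines(g$reads)
  seqs <- reads[!startsWith(reads, ">")]
  expect_identical(length(seqs), 50L)
  expect_true(all(nchar(seqs) == 40L))
})

test_that("duplicate marking matches the generator's positional ground truth", {
  local_workspace()
  ts <- toy_setup(seed = 21, n_reads = 100, dup_fraction = 0.2)
  md <- out(ts$src %>>% ts$st$align() %>>% ts$st$sort() %>>%
              ts$st$mark_dups(), "marked.tal")
  execute_workflow(md)
  rec <- read.delim("marked.tal", header = FALSE,
                    col.names = c("id", "contig", "pos", "flags", "seq"))
  expect_identical(sum(rec$flags == "dup"), ts$g$n_duplicate_records)
  # dedup removes exactly those records
  dd <- out(ts$src %>>% ts$st$align() %>>% ts$st$sort() %>>% ts$st$dedup(),
            "dedup.tal")
  execute_workflow(dd)
  expect_identical(length(readLines("dedup.tal")),
                   nrow(rec) - ts$g$n_duplicate_records)
})

test_that("sorted output is ordered and round-trips through the dialect", {
  local_workspace()
  ts <- toy_setup(n_reads = 60)
  srt <- out(ts$src %>>% ts$st$align() %>>% ts$st$sort(), "sorted.tal")
  execute_workflow(srt)
  rec <- read.delim("sorted.tal", header = FALSE,
                    col.names = c("id", "contig", "pos", "flags", "seq"))
  o <- order(rec$contig, rec$pos, rec$id, method = "radix")
  expect_identical(o, seq_len(nrow(rec)))
  # fixmates is a dialect-checking pass-through: byte-identical round-trip
  fm <- out(ts$src %>>% ts$st$align() %>>% ts$st$fix_mates(), "fm.tal")
  al <- out(ts$src %>>% ts$st$align(), "al.tal")
  execute_workflow(list(fm, al))
  expect_identical(readLines("fm.tal"), readLines("al.tal"))
})

test_that("round-robin chunking gives the documented shard sizes", {
  local_workspace()
  a <- toy_algebra(); st <- toy_stages(a)
  write_fa <- function(path, n) {
    writeLines(as.vector(rbind(sprintf(">s%d", 1:n),
                               strrep("ACGT", 5))), path)
  }
  write_fa("ten.fa", 10)
  wf <- out(flow_source("ten.fa", "ToyFasta", a) %>>% st$chunk(n = 3),
            c("s1.fa", "s2.fa", "s3.fa"))
  execute_workflow(wf)
  sizes <- vapply(sprintf("s%d.fa", 1:3), function(f)
    sum(startsWith(readLines(f), ">")), 0L)
  expect_identical(unname(sizes), c(4L, 3L, 3L))
})

test_that("toy builders reject wrong input dialects loudly", {
  local_workspace()
  tool <- system.file("tools", "toytool.R", package = "typedflow")
  g <- gen_reads("d", seed = 1, n_reads = 20, n_contigs = 2,
                 variants_per_contig = 1)
  # sorting a FASTA file: dialect violation, non-zero exit
  st_fa <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"),
            shQuote(c("--vanilla", tool, "sort", g$reads, "x.tal")),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(st_fa, "status")))
  expect_true(any(grepl("FASTA", st_fa)))
  # calling on an unsorted alignment: sortedness violation
  writeLines(c("r2\tc1\t9\t.\tACGT", "r1\tc1\t2\t.\tACGT"), "unsorted.tal")
  st_un <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"),
            shQuote(c("--vanilla", tool, "call", g$ref, "unsorted.tal",
                      "y.vcf")),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(st_un, "status")))
  expect_true(any(grepl("sorted", st_un)))
})

test_that("the linear toy pipeline recovers planted variants exactly", {
  local_workspace()
  ts <- toy_setup(seed = 42, n_reads = 150)
  execute_workflow(example1_expr(ts))
  calls <- read_vcf_calls("output.vcf")
  truth <- ts$g$variants
  expect_identical(paste(calls$contig, calls$pos, calls$alt),
                   paste(truth$contig, truth$pos, truth$alt))
  # VCF dialect shape: headers then the 8 mandatory columns
  ln <- readLines("output.vcf")
  expect_identical(ln[1], "##fileformat=VCFv4.2")
  hdr <- grep("^#CHROM", ln, value = TRUE)
  expect_length(strsplit(hdr, "\t")[[1]], 8)
})
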