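test_that("sources keep their paths and reject bad construction", {
  a <- toy_algebra()
  s <- flow_source(c("r1.fq", "r2.fq"), "ToyFasta", a)
  expect_identical(output_paths(s), c("r1.fq", "r2.fq"))
  expect_error(flow_source(character(), "ToyFasta", a),
               class = "tf_construction")
  expect_error(flow_source("a.fa", "NotATag", a), class = "tf_unknown_tag")
})

test_that("source tags are closed under implication", {
  a <- toy_algebra()
  s <- flow_source("a.fa", c("ToyBam", "DeDuped"), a)
  expect_true("DupsMarked" %in% effective_tags(s))
})

test_that("composition is left-associative and never throws on tag mismatch", {
  local_workspace()
  ts <- toy_setup(n_reads = 40)
  chained <- ts$src %>>% ts$st$align() %>>% ts$st$sort()
  explicit <- compose(compose(ts$src, ts$st$align()), ts$st$sort())
  expect_identical(output_paths(chained), output_paths(explicit))
  expect_identical(stage_path(chained), c("align", "sort"))
  # a mis-tagged chain builds fine; validate() is the gate
  bad <- ts$src %>>% ts$st$sort()
  expect_s3_class(bad, "tf_compose")
})

test_that("output arity follows the stage and bundles concatenate in order", {
  local_workspace()
  ts <- toy_setup(n_reads = 40)
  one <- ts$src %>>% ts$st$align()
  expect_length(output_paths(one), 1)
  ch <- ts$src %>>% ts$st$chunk(n = 4)
  expect_length(output_paths(ch), 4)
  b <- with_all(list(one, ch))
  expect_identical(output_paths(b), c(output_paths(one), output_paths(ch)))
})

test_that("effective tags: stage outputs, propagation, transients, intersection", {
  local_workspace()
  ts <- toy_setup(n_reads = 40)
  aligned <- ts$src %>>% ts$st$align()
  sorted <- aligned %>>% ts$st$sort()
  expect_true(all(c("ToyBam", "Sorted") %in% effective_tags(sorted)))
  # sorting does not survive a non-order-preserving stage by default
  expect_false("Sorted" %in% effective_tags(aligned))
  # dedup's tag propagates to every downstream node, and implies DupsMarked
  deduped <- sorted %>>% ts$st$dedup()
  called <- deduped %>>% ts$st$call()
  expect_true(all(c("DeDuped", "DupsMarked") %in% effective_tags(called)))
  # transient: mark_dups preserves Sorted
  md <- sorted %>>% ts$st$mark_dups()
  expect_true("Sorted" %in% effective_tags(md))
  # bundle guarantees only the intersection
  both <- with_all(list(sorted, aligned))
  expect_true("ToyBam" %in% effective_tags(both))
  expect_false("Sorted" %in% effective_tags(both))
})

test_that("purity: repeated calls give identical paths and tags", {
  local_workspace()
  ts <- toy_setup(n_reads = 40)
  wf <- ts$src %>>% ts$st$align() %>>% ts$st$sort()
  expect_identical(output_paths(wf), output_paths(wf))
  expect_identical(effective_tags(wf), effective_tags(wf))
})

test_that("builders can reference prior products by tag", {
  local_workspace()
  ts <- toy_setup(n_reads = 40)
  sorted <- ts$src %>>% ts$st$align() %>>% ts$st$sort()
  md <- sorted %>>% ts$st$mark_dups()
  # nearest node holding both tags is the mark_dups node itself; the sort
  # node is found when DupsMarked is not required
  expect_identical(upstream_products(md, c("ToyBam", "Sorted")),
                   output_paths(md))
  expect_identical(upstream_products(sorted, c("ToyBam", "Sorted")),
                   output_paths(sorted))
  expect_identical(upstream_products(md, "ToyFasta"), output_paths(ts$src))
  # vacuous predicate: the node itself
  expect_identical(upstream_products(md, character()), output_paths(md))
  expect_identical(upstream_products(md, "ToyVcf"), character())
})

test_that("define_stage checks its signature against the algebra", {
  a <- toy_algebra()
  noop <- function(inputs, outputs, upstream, stg, ctx) NULL
  expect_error(
    define_stage(a, "bad", output_tags = "Sorted", builder = noop),
    class = "tf_definition")           # Sorted has no extension
  expect_error(
    define_stage(a, "bad", output_tags = "NoSuchTag", builder = noop),
    class = "tf_unknown_tag")
  ctor <- define_stage(a, "ok", "ToyBam", c("ToyBam", "Sorted"),
                       builder = noop, defaults = list(level = 1))
  s <- ctor(level = 9, threads = 4)
  expect_s3_class(s, "tf_stage")
  expect_identical(s$params$level, 9)
  expect_identical(s$threads, 4L)
  expect_error(stage("bad name!", output_tags = "x", builder = noop),
               class = "tf_construction")
})
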