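test_that("tag declaration, extensions and redeclaration guard", {
  a <- tag_algebra()
  a <- declare_tag(a, "IsBam", extension = "bam")
  a <- declare_tag(a, "Sorted")   # metadata-only tag, no extension
  expect_identical(typedflow:::tag_extension(a, "IsBam"), "bam")
  expect_null(typedflow:::tag_extension(a, "Sorted"))
  expect_error(declare_tag(a, "IsBam"), class = "tf_redeclared_tag")
  expect_error(add_implication(a, "IsBam", "Nope"), class = "tf_unknown_tag")
})

test_that("implication closure honours deduplicated => duplicates-marked", {
  a <- toy_algebra()
  expect_true("DupsMarked" %in% close_tags(a, "DeDuped"))
  expect_identical(close_tags(a, character()), character())
})

test_that("closure chains through multiple implications", {
  a <- tag_algebra()
  for (t in c("a", "b", "c")) a <- declare_tag(a, t)
  a <- add_implication(a, "a", "b")
  a <- add_implication(a, "b", "c")
  expect_setequal(close_tags(a, "a"), c("a", "b", "c"))
})

test_that("closure is a closure operator on random implication graphs", {
  # oracle: brute-force BFS over the implication edge list
  bfs_close <- function(edges, tags) {
    out <- tags
    repeat {
      nxt <- unique(unlist(lapply(edges, function(e)
        if (e[1] %in% out) e[2] else NULL)))
      new <- setdiff(nxt, out)
      if (!length(new)) break
      out <- c(out, new)
    }
    sort(out, method = "radix")
  }
  set.seed(42)
  for (trial in 1:20) {
    ids <- paste0("t", seq_len(sample(5:20, 1)))
    a <- tag_algebra()
    for (t in ids) a <- declare_tag(a, t)
    edges <- list()
    for (k in seq_len(sample(3:25, 1))) {
      e <- sample(ids, 2)
      a <- add_implication(a, e[1], e[2])
      edges[[length(edges) + 1]] <- e
    }
    s <- sample(ids, sample.int(length(ids), 1))
    cl <- close_tags(a, s)
    expect_identical(cl, bfs_close(edges, sort(unique(s))))   # oracle
    expect_true(all(s %in% cl))                               # extensive
    expect_identical(close_tags(a, cl), cl)                   # idempotent
    s2 <- unique(c(s, sample(ids, 1)))
    expect_true(all(cl %in% close_tags(a, s2)))               # monotone
  }
})

test_that("the bundled ontology subset loads and exposes ancestors", {
  onto <- load_edam(system.file("extdata", "edam_subset.tsv",
                                package = "typedflow"))
  expect_gt(length(onto$terms), 40)
  anc <- typedflow:::ontology_ancestors(onto, "format_1931")
  expect_true(all(c("format_1930", "format_2044", "format_1915") %in% anc))
})

test_that("malformed ontologies are rejected, empty files tolerated", {
  local_workspace()
  writeLines("x\tSelfish\tx", "self.tsv")
  expect_error(load_edam("self.tsv"), class = "tf_malformed_ontology")
  writeLines(c("a\tA\tb", "b\tB\ta"), "cycle.tsv")
  expect_error(load_edam("cycle.tsv"), class = "tf_malformed_ontology")
  writeLines("a\tA\tmissing", "dangle.tsv")
  expect_error(load_edam("dangle.tsv"), class = "tf_missing_parent")
  writeLines(character(), "empty.tsv")
  expect_length(load_edam("empty.tsv")$terms, 0)
})

test_that("attaching an ontology term installs the whole ancestor chain", {
  onto <- load_edam(system.file("extdata", "edam_subset.tsv",
                                package = "typedflow"))
  a <- declare_tag(tag_algebra(), "MyType", extension = "fq")
  a <- attach_edam(a, "MyType", "format_1931", onto)
  cl <- close_tags(a, "MyType")
  expect_true(all(c("FastqIllumina", "Fastq", "SequenceRecordFormat",
                    "Format") %in% cl))
  # root term: adds exactly that term
  b <- declare_tag(tag_algebra(), "Fmt")
  b <- attach_edam(b, "Fmt", "format_1915", onto)
  expect_setequal(close_tags(b, "Fmt"), c("Fmt", "Format"))
  expect_error(attach_edam(a, "MyType", "format_9999", onto),
               class = "tf_unknown_term")
})

test_that("ontology closure equals graph-reachability oracle for every term", {
  onto <- load_edam(system.file("extdata", "edam_subset.tsv",
                                package = "typedflow"))
  reach <- function(id) {      # independent traversal on the raw term table
    seen <- character(); frontier <- id
    while (length(frontier)) {
      ps <- unique(unlist(lapply(onto$terms[frontier], `[[`, "parents")))
      frontier <- setdiff(ps, seen)
      seen <- union(seen, frontier)
    }
    sort(vapply(seen, function(t) typedflow:::term_tag_id(onto, t), "",
                USE.NAMES = FALSE), method = "radix")
  }
  for (id in names(onto$terms)) {
    a <- declare_tag(tag_algebra(), "X")
    a <- attach_edam(a, "X", id, onto)
    got <- setdiff(close_tags(a, "X"),
                   c("X", typedflow:::term_tag_id(onto, id)))
    expect_identical(got, reach(id))
  }
})

test_that("valued tags propagate to any downstream stage and detect conflicts", {
  local_workspace()
  ts <- toy_setup()
  wf <- ts$src %>>% ts$st$align() %>>% ts$st$fix_mates() %>>% ts$st$sort()
  expect_identical(get_valued(wf, "Referenced"), ts$g$ref)
  expect_true("Referenced" %in% effective_tags(wf))

  plain <- flow_source("x.fa", "ToyFasta", ts$algebra)
  expect_error(get_valued(plain, "Referenced"), class = "tf_absent_value")

  s1 <- flow_source("a.fa", c("ToyFasta", Referenced = "ref.fa"), ts$algebra)
  s2 <- flow_source("b.fa", c("ToyFasta", Referenced = "ref.fa"), ts$algebra)
  s3 <- flow_source("c.fa", c("ToyFasta", Referenced = "other.fa"), ts$algebra)
  expect_identical(get_valued(with_all(list(s1, s2)), "Referenced"), "ref.fa")
  expect_error(get_valued(with_all(list(s1, s3)), "Referenced"),
               class = "tf_value_conflict")
})

test_that("tag algebras load from a YAML manifest", {
  local_workspace()
  writeLines(c(
    "tags:",
    "  - {id: IsBam, extension: bam}",
    "  - {id: Sorted}",
    "  - {id: DeDuped, propagating: true}",
    "  - {id: DupsMarked}",
    "implications:",
    "  - [DeDuped, DupsMarked]"), "tags.yaml")
  a <- algebra_from_yaml("tags.yaml")
  expect_true("DupsMarked" %in% close_tags(a, "DeDuped"))
  expect_identical(typedflow:::tag_extension(a, "IsBam"), "bam")
  expect_true("DeDuped" %in% typedflow:::propagating_tags(a))
})
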