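# Engine tests use small in-process rulesets (synth_rule in the helper):
# each action concatenates its input files and appends its own name, so any
# upstream content change propagates observably.

test_that("a second build with no changes rebuilds nothing", {
  dir <- local_workspace()
  writeLines("in", "a.txt")
  rs <- synth_ruleset(list(
    synth_rule("one", "b.txt", "a.txt"),
    synth_rule("two", "c.txt", "b.txt")), wanted = "c.txt")
  r1 <- build(rs)
  expect_identical(rules_with_status(r1, "built"), 2L)
  r2 <- build(rs)
  expect_identical(rules_with_status(r2, "built"), 0L)
  expect_identical(rules_with_status(r2, "skipped-up-to-date"), 2L)
})

test_that("deleting an intermediate rebuilds its rule and the descendants", {
  local_workspace()
  writeLines("in", "a.txt")
  rs <- synth_ruleset(list(
    synth_rule("one", "b.txt", "a.txt"),
    synth_rule("two", "c.txt", "b.txt"),
    synth_rule("three", "d.txt", "c.txt")), wanted = "d.txt")
  build(rs)
  unlink("c.txt")
  r <- build(rs)
  rebuilt <- r$rows$rule[r$rows$status == "built"]
  expect_setequal(rebuilt, c("two", "three"))
})

test_that("perturbing a source rebuilds exactly its consumers", {
  local_workspace()
  writeLines("in", "a.txt")
  writeLines("other", "z.txt")
  rs <- synth_ruleset(list(
    synth_rule("fromA", "b.txt", "a.txt"),
    synth_rule("fromZ", "y.txt", "z.txt"),
    synth_rule("join", "c.txt", c("b.txt", "y.txt"))), wanted = "c.txt")
  build(rs)
  writeLines("changed", "a.txt")
  r <- build(rs)
  rebuilt <- r$rows$rule[r$rows$status == "built"]
  expect_setequal(rebuilt, c("fromA", "join"))
  expect_identical(r$rows$status[r$rows$rule == "fromZ"], "skipped-up-to-date")
})

test_that("rebuild sets match the DAG-descendant oracle on random graphs", {
  dir <- local_workspace()
  for (trial in 1:8) {
    sub <- file.path(dir, sprintf("t%d", trial))
    dir.create(sub)
    dag <- random_dag_ruleset(n = sample(8:30, 1), dir = sub,
                              seed = 1000 + trial)
    build(dag$ruleset)
    victim <- sample(c(dag$src, dag$paths[-length(dag$paths)]), 1)
    writeLines(sprintf("perturbed-%d", trial), victim)
    r <- build(dag$ruleset)
    rebuilt <- sort(r$rows$rule[r$rows$status == "built"])
    expect_identical(rebuilt, sort(descendant_rules(dag, victim)),
                     label = sprintf("trial %d victim %s", trial, victim))
  }
})

test_that("dependency cycles are reported with the paths involved", {
  local_workspace()
  rs <- synth_ruleset(list(
    synth_rule("a", "x.txt", "y.txt"),
    synth_rule("b", "y.txt", "x.txt")), wanted = "x.txt")
  expect_error(build(rs), class = "tf_cycle")
})

test_that("missing inputs with no rule are reported up front", {
  local_workspace()
  rs <- synth_ruleset(list(synth_rule("a", "x.txt", "ghost.txt")),
                      wanted = "x.txt")
  expect_error(build(rs), class = "tf_missing_rule")
})

test_that("pattern rules build side products on demand, explicit rules win", {
  local_workspace()
  writeLines("in", "a.txt")
  indexed <- function(name, outputs, deps) {
    list(name = name, outputs = outputs, deps = deps,
         action = function(ctx) {
           ctx$need(paste0(deps[1], ".idx"))   # dynamic, mid-run
           writeLines(c(readLines(deps[1]),
                        readLines(paste0(deps[1], ".idx"))), outputs[1])
         })
  }
  rs <- synth_ruleset(list(
    synth_rule("mk", "b.txt", "a.txt"),
    indexed("use", "c.txt", "b.txt")), wanted = "c.txt")
  rs <- add_pattern_rule(rs, "*.idx", function(stem, output, ctx) {
    writeLines(paste0("index-of-", basename(stem)), output)
  })
  build(rs)
  expect_identical(readLines("b.txt.idx"), "index-of-b.txt")
  expect_identical(readLines("c.txt"), c("in", "mk", "index-of-b.txt"))
  # second run: nothing rebuilt even with the dynamic dep recorded
  r2 <- build(rs)
  expect_identical(rules_with_status(r2, "built"), 0L)
  # explicit rule takes precedence over a matching pattern
  rs2 <- synth_ruleset(list(synth_rule("explicit", "q.txt.idx", "a.txt")),
                       wanted = "q.txt.idx")
  rs2 <- add_pattern_rule(rs2, "*.txt.idx", function(stem, output, ctx)
    writeLines("from-pattern", output))
  build(rs2)
  expect_identical(readLines("q.txt.idx"), c("in", "explicit"))
  # two matching patterns are ambiguous
  rs3 <- synth_ruleset(list(indexed("use", "m.txt", "a.txt")),
                       wanted = "m.txt")
  rs3 <- add_pattern_rule(rs3, "*.idx", function(s, o, c) writeLines("1", o))
  rs3 <- add_pattern_rule(rs3, "a.*.idx", function(s, o, c) writeLines("2", o))
  expect_error(build(rs3), class = "tf_build_failed")
})

test_that("a changed recorded dynamic dependency triggers a rebuild", {
  local_workspace()
  writeLines("v1", "side.txt")
  rs <- synth_ruleset(list(
    list(name = "dyn", outputs = "out.txt", deps = character(),
         action = function(ctx) {
           ctx$need("side.txt")
           writeLines(readLines("side.txt"), "out.txt")
         })), wanted = "out.txt")
  build(rs)
  expect_identical(readLines("out.txt"), "v1")
  writeLines("v2", "side.txt")
  r <- build(rs)
  expect_identical(rules_with_status(r, "built"), 1L)
  expect_identical(readLines("out.txt"), "v2")
})

test_that("failures stop dispatch, persist completed work, and resume", {
  local_workspace()
  writeLines("in", "a.txt")
  flaky <- local({
    function(ctx) {
      if (!file.exists("armed.flag")) stop("injected failure")
      writeLines("ok", "c.txt")
    }
  })
  rs <- synth_ruleset(list(
    synth_rule("good", "b.txt", "a.txt"),
    list(name = "flaky", outputs = "c.txt", deps = "b.txt", action = flaky),
    synth_rule("after", "d.txt", "c.txt")), wanted = "d.txt")
  expect_error(build(rs), class = "tf_build_failed")
  expect_true(file.exists("b.txt"))
  expect_false(file.exists("d.txt"))
  file.create("armed.flag")
  r <- build(rs)                      # resumes: good is already up to date
  rows <- r$rows
  expect_identical(rows$status[rows$rule == "good"], "skipped-up-to-date")
  expect_setequal(rows$rule[rows$status == "built"], c("flaky", "after"))
})

test_that("parallel builds give byte-identical outputs to serial ones", {
  dir <- local_workspace()
  mk <- function(sub) {
    d <- file.path(dir, sub); dir.create(d)
    dag <- random_dag_ruleset(n = 12, dir = d, seed = 99)
    dag
  }
  d1 <- mk("serial"); d4 <- mk("par")
  build(d1$ruleset, jobs = 1)
  build(d4$ruleset, jobs = 4)
  for (i in seq_along(d1$paths)) {
    expect_identical(readLines(d4$paths[i]), readLines(d1$paths[i]))
  }
})

test_that("a corrupt database line degrades to rebuild, never wrong reuse", {
  local_workspace()
  writeLines("in", "a.txt")
  rs <- synth_ruleset(list(synth_rule("one", "b.txt", "a.txt")),
                      wanted = "b.txt")
  db <- file.path(tf_workdir(), "build-db.jsonl")
  build(rs)
  writeLines("{this is not json", db)
  r <- build(rs)
  expect_identical(rules_with_status(r, "built"), 1L)
  expect_identical(readLines("b.txt"), c("in", "one"))
})

test_that("build reports serialise to JSON with per-rule status", {
  local_workspace()
  writeLines("in", "a.txt")
  rs <- synth_ruleset(list(synth_rule("one", "b.txt", "a.txt")),
                      wanted = "b.txt")
  rep <- build(rs)
  j <- jsonlite::fromJSON(file.path(tf_workdir(), "last-report.json"))
  expect_identical(j$digest_algorithm, "sha1/base32")
  expect_identical(j$rules$status, "built")
  expect_false(j$failed)
})
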