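# Shared fixtures: every test works in a throwaway directory with the
# managed workdir option pointed inside it.

local_workspace <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  withr::local_dir(dir, .local_envir = env)
  withr::local_options(typedflow.workdir = file.path(dir, "_typedflow"),
                       .local_envir = env)
  dir
}

toy_setup <- function(seed = 7, n_reads = 120,
                      n_contigs = if (n_reads >= 100) 5L else 2L,
                      variants_per_contig = if (n_reads >= 100) 2L else 1L,
                      ...) {
  g <- gen_reads("data", seed = seed, n_reads = n_reads,
                 n_contigs = n_contigs,
                 variants_per_contig = variants_per_contig, ...)
  a <- toy_algebra()
  list(g = g, algebra = a, st = toy_stages(a),
       src = flow_source(g$reads, c("ToyFasta", Referenced = g$ref), a))
}

# the linear resequencing chain of the worked example
example1_expr <- function(ts, final = "output.vcf") {
  wf <- ts$src %>>% ts$st$align() %>>% ts$st$fix_mates() %>>%
    ts$st$sort() %>>% ts$st$mark_dups() %>>% ts$st$call()
  out(wf, final)
}

read_vcf_calls <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) return(data.frame(contig = character(), pos = integer(),
                                     alt = character()))
  f <- read.table(text = ln, sep = "\t", stringsAsFactors = FALSE)
  data.frame(contig = f$V1, pos = f$V2, alt = f$V5, stringsAsFactors = FALSE)
}

# small in-process rulesets for engine tests: each rule concatenates its
# inputs plus its own name (content change in any input propagates)
synth_rule <- function(name, outputs, deps) {
  force(name); force(outputs); force(deps)
  list(name = name, outputs = outputs, deps = deps,
       action = function(ctx) {
         txt <- unlist(lapply(deps, readLines))
         for (o in outputs) writeLines(c(txt, name), o)
       })
}

synth_ruleset <- function(rules, wanted = character()) {
  rs <- typedflow::compile(list())  # empty, valid ruleset shell
  rs$rules <- rules
  rs$wanted <- wanted
  rs
}

# random linear-ish DAG over n rules rooted at one source file; returns
# ruleset plus adjacency for the reachability oracle
random_dag_ruleset <- function(n, dir, seed) {
  set.seed(seed)
  src <- file.path(dir, "src.txt")
  writeLines("seed", src)
  rules <- vector("list", n)
  paths <- file.path(dir, sprintf("n%02d.txt", seq_len(n)))
  parents <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- if (i == 1) character() else sample(paths[seq_len(i - 1)],
                                                size = sample(1:min(3, i - 1), 1))
    deps <- unique(c(src[i == 1 || runif(1) < 0.3], pool))
    if (!length(deps)) deps <- src
    parents[[i]] <- deps
    rules[[i]] <- synth_rule(sprintf("n%02d", i), paths[i], deps)
  }
  list(ruleset = synth_ruleset(rules, wanted = paths),
       paths = paths, src = src, parents = parents)
}

# rules whose rebuild we expect after perturbing `path`: the producer of the
# file (if any) plus everything reachable downstream -- computed by plain
# graph search, independent of the engine
descendant_rules <- function(dag, path) {
  n <- length(dag$paths)
  affected <- rep(FALSE, n)
  if (path %in% dag$paths) affected[match(path, dag$paths)] <- TRUE
  repeat {
    grew <- FALSE
    for (i in seq_len(n)) {
      if (affected[i]) next
      deps <- dag$parents[[i]]
      hit <- any(deps == path) ||
        any(affected[match(intersect(deps, dag$paths), dag$paths)])
      if (hit) { affected[i] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  sprintf("n%02d", which(affected))
}
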