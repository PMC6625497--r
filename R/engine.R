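# Make-like incremental build engine. Rules are scheduled topologically;
# a rule reruns iff its outputs are missing or perturbed, its fingerprint
# changed, any recorded dependency's content digest changed, or any
# dependency was itself rebuilt this run. Freshness uses content digests
# (SHA-1 of file bytes), never mtimes, so restores and copies are handled
# robustly. State is persisted to a JSON-lines database after every rule,
# giving re-entrancy: an interrupted build resumes from the last completed
# rule.

file_digest <- function(path) digest::digest(file = path, algo = "sha1")

rule_fingerprint <- function(rule) {
  digest::digest(list(rule$name, rule$outputs, rule$deps), algo = "sha1")
}

# ---- build database (JSON-lines, append-oriented, last entry wins) --------

db_load <- function(path) {
  db <- new.env(parent = emptyenv())
  if (!is.null(path) && file.exists(path)) {
    for (ln in readLines(path, warn = FALSE)) {
      ent <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
      if (is.null(ent) || is.null(ent$path)) next  # corrupt line: rebuild, never reuse
      assign(ent$path, list(digest = ent$digest,
                            fingerprint = ent$fingerprint %||% NA_character_,
                            deps = as.list(ent$deps)),
             envir = db)
    }
  }
  db
}

db_append <- function(path, entries) {
  if (is.null(path) || !length(entries)) return(invisible(NULL))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(entries, function(e) {
    jsonlite::toJSON(list(path = e$path, digest = e$digest,
                          fingerprint = e$fingerprint, deps = e$deps),
                     auto_unbox = TRUE, null = "null")
  }, "")
  cat(paste0(lines, "\n", collapse = ""), file = path, append = TRUE)
  invisible(NULL)
}

db_entry <- function(db, path) if (exists(path, envir = db)) get(path, envir = db) else NULL

# ---- pattern rules ---------------------------------------------------------

#' Add an extrinsic pattern rule
#'
#' Make-style rule keyed on an output filename pattern: any needed path
#' matching the glob (one `*` stem wildcard) and not claimed by an explicit
#' rule is buildable by `action`. Typical use: side products such as index
#' files, removing the need for an explicit index stage in the pipeline.
#'
#' @param ruleset A `tf_ruleset` from [compile()].
#' @param pattern Glob with exactly one `*`, e.g. `"*.tal.idx"`.
#' @param action Function `(stem, output, ctx)` producing the file.
#' @return The updated ruleset.
#' @export
add_pattern_rule <- function(ruleset, pattern, action) {
  stopifnot(inherits(ruleset, "tf_ruleset"))
  if (lengths(regmatches(pattern, gregexpr("*", pattern, fixed = TRUE))) != 1L)
    tf_stop("construction", "pattern must contain exactly one '*': %s", pattern)
  ruleset$pattern_rules[[length(ruleset$pattern_rules) + 1L]] <-
    list(pattern = pattern, action = action)
  ruleset
}

pattern_stem <- function(pattern, path) {
  rx <- paste0("^", gsub("\\*", "(.+)", gsub("([.\\\\+?^$(){}\\[\\]|])",
                                             "\\\\\\1", pattern)), "$")
  m <- regmatches(path, regexec(rx, path))[[1]]
  if (length(m) == 2L) m[2] else NULL
}

match_pattern <- function(ruleset, path) {
  hits <- Filter(function(pr) !is.null(pattern_stem(pr$pattern, path)),
                 ruleset$pattern_rules)
  if (length(hits) > 1L)
    tf_stop("ambiguous_pattern", "multiple pattern rules match '%s': %s", path,
            paste(vapply(hits, `[[`, "", "pattern"), collapse = ", "))
  if (length(hits)) hits[[1]] else NULL
}

# ---- build -----------------------------------------------------------------

new_report_row <- function(rule, status, seconds = NA_real_, error = NA_character_) {
  data.frame(rule = rule$name, output = rule$outputs[1], status = status,
             seconds = seconds, error = error, stringsAsFactors = FALSE)
}

#' Build targets from a ruleset
#'
#' Topologically schedules the rules reachable from `targets`. A rule is
#' skipped iff all its outputs exist with unchanged content digests, its
#' fingerprint matches the database, and every recorded dependency (static
#' and dynamic) is unchanged and itself up to date. Independent ready rules
#' run concurrently up to `jobs` (results identical to a serial build);
#' ready rules are dispatched in lexicographic order of first output for
#' reproducible reports. After every completed rule the database is
#' persisted, so an interrupted build resumes where it stopped.
#'
#' @param ruleset A `tf_ruleset`.
#' @param targets Paths to bring up to date (defaults to `ruleset$wanted`).
#' @param jobs Maximum number of concurrently running rules.
#' @param db_path Build-database file (JSON-lines); `NULL` disables
#'   persistence.
#' @param executor Executor handle passed to builders (see
#'   [local_executor()], [script_executor()]).
#' @param workdir Managed work directory (for the default database path and
#'   report file).
#' @param keep_going Continue scheduling after a failure (default: stop
#'   dispatching, drain running jobs).
#' @param verbose Log per-rule start/finish lines to stderr.
#' @return A `tf_report` (invisibly carries per-rule status, timings and
#'   dependency edges).
#' @export
build <- function(ruleset, targets = NULL, jobs = 1L,
                  db_path = file.path(workdir, "build-db.jsonl"),
                  executor = local_executor(), workdir = tf_workdir(),
                  keep_going = FALSE, verbose = FALSE) {
  stopifnot(inherits(ruleset, "tf_ruleset"))
  targets <- targets %||% ruleset$wanted
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  db <- db_load(db_path)
  digest_cache <- new.env(parent = emptyenv())
  cur_digest <- function(p) {
    d <- digest_cache[[p]]
    if (is.null(d)) {
      d <- if (file.exists(p)) file_digest(p) else NA_character_
      assign(p, d, envir = digest_cache)
    }
    d
  }
  log <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  out2rule <- new.env(parent = emptyenv())
  for (i in seq_along(ruleset$rules)) {
    for (p in ruleset$rules[[i]]$outputs) {
      if (!is.null(out2rule[[p]]))
        tf_stop("construction", "two rules declare the same output '%s'", p)
      assign(p, i, envir = out2rule)
    }
  }
  rule_of <- function(path) { i <- out2rule[[path]]; if (is.null(i)) NULL else i }

  # --- closure of rules needed for the targets (static + recorded deps) ----
  needed <- integer()
  frontier <- targets
  seen_paths <- character()
  while (length(frontier)) {
    p <- frontier[[1]]; frontier <- frontier[-1]
    if (p %in% seen_paths) next
    seen_paths <- c(seen_paths, p)
    i <- rule_of(p)
    if (is.null(i)) {
      if (is.null(match_pattern(ruleset, p)) && !file.exists(p))
        tf_stop("missing_rule", "no rule builds '%s' and the file does not exist", p)
      next
    }
    if (!i %in% needed) {
      needed <- c(needed, i)
      r <- ruleset$rules[[i]]
      recorded <- db_entry(db, r$outputs[1])
      frontier <- c(frontier, r$deps,
                    setdiff(names(recorded$deps %||% list()), r$deps))
    }
  }
  needed <- sort(needed)
  rules <- ruleset$rules[needed]
  n <- length(rules)

  # --- dependency edges among scheduled rules + cycle check ----------------
  producer <- new.env(parent = emptyenv())
  for (j in seq_len(n)) for (p in rules[[j]]$outputs) assign(p, j, envir = producer)
  preds <- lapply(rules, function(r) {
    recorded <- db_entry(db, r$outputs[1])
    deps <- union(r$deps, names(recorded$deps %||% list()))
    unique(unlist(lapply(deps, function(p) producer[[p]])))
  })
  indeg <- lengths(preds)
  succs <- vector("list", n)
  for (j in seq_len(n)) for (p in preds[[j]])
    succs[[p]] <- c(succs[[p]], j)
  topo <- integer()
  ready <- which(indeg == 0L)
  indeg2 <- indeg
  while (length(ready)) {
    j <- ready[[1]]; ready <- ready[-1]
    topo <- c(topo, j)
    for (s in succs[[j]]) {
      indeg2[s] <- indeg2[s] - 1L
      if (indeg2[s] == 0L) ready <- c(ready, s)
    }
  }
  if (length(topo) < n) {
    cyc <- setdiff(seq_len(n), topo)
    tf_stop("cycle", "dependency cycle involving: %s",
            paste(unlist(lapply(rules[cyc], function(r) r$outputs[1])), collapse = ", "))
  }

  # --- dirtiness, in topological order -------------------------------------
  dirty <- logical(n)
  for (j in topo) {
    r <- rules[[j]]
    fp <- rule_fingerprint(r)
    ent <- db_entry(db, r$outputs[1])
    d <- FALSE
    if (is.null(ent) || !identical(ent$fingerprint, fp)) d <- TRUE
    if (!d) for (p in r$outputs) {
      e <- db_entry(db, p)
      if (is.null(e) || !file.exists(p) || !identical(cur_digest(p), e$digest)) { d <- TRUE; break }
    }
    if (!d) {
      deps <- union(r$deps, names(ent$deps %||% list()))
      for (p in deps) {
        pr <- producer[[p]]
        if (!is.null(pr) && dirty[pr]) { d <- TRUE; break }
        if (!file.exists(p)) { d <- TRUE; break }
        rec <- ent$deps[[p]]
        if (is.null(rec) || !identical(cur_digest(p), rec)) { d <- TRUE; break }
      }
    }
    dirty[j] <- d
  }

  # --- execution context shared by actions ---------------------------------
  report <- list()
  new_entries_of <- function(r, dyn_deps) {
    fp <- rule_fingerprint(r)
    all_deps <- unique(c(r$deps, dyn_deps))
    depmap <- stats::setNames(
      lapply(all_deps, function(p) if (file.exists(p)) file_digest(p) else NA_character_),
      all_deps)
    lapply(r$outputs, function(p) {
      if (!file.exists(p))
        tf_stop("build", "rule '%s' finished without producing '%s'", r$name, p)
      list(path = p, digest = file_digest(p), fingerprint = fp, deps = depmap)
    })
  }

  make_ctx <- function(rule) {
    ctx <- new.env(parent = emptyenv())
    ctx$executor <- executor
    ctx$workdir <- workdir
    ctx$verbose <- verbose
    ctx$dynamic_deps <- character()
    ctx$extra_entries <- list()
    ctx$need <- function(paths) {
      for (p in paths) {
        i <- rule_of(p)
        if (!is.null(i)) {
          # explicit rules are scheduled via static deps; a dynamic need of
          # one must already be satisfied in a consistent ruleset
          if (!file.exists(p))
            tf_stop("build", "dynamic need of unscheduled rule output '%s'", p)
        } else {
          pr <- match_pattern(ruleset, p)
          if (!is.null(pr)) {
            ensure_pattern_product(p, pr, ctx)
          } else if (!file.exists(p)) {
            tf_stop("missing_rule",
                    "needed path '%s' has no rule and does not exist", p)
          }
        }
        ctx$dynamic_deps <- union(ctx$dynamic_deps, p)
      }
      invisible(paths)
    }
    ctx
  }

  ensure_pattern_product <- function(path, pr, ctx) {
    pfp <- digest::digest(list("pattern", pr$pattern), algo = "sha1")
    ent <- db_entry(db, path)
    fresh <- file.exists(path) && !is.null(ent) &&
      identical(ent$fingerprint, pfp) && identical(file_digest(path), ent$digest)
    if (!fresh) {
      # write via temp + rename: concurrent builders of the same side
      # product converge on identical content without torn files
      stem <- pattern_stem(pr$pattern, path)
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      pr$action(stem, path, ctx)
      if (!file.exists(path))
        tf_stop("build", "pattern rule '%s' did not produce '%s'", pr$pattern, path)
    }
    ctx$extra_entries <- c(ctx$extra_entries, list(list(
      path = path, digest = file_digest(path), fingerprint = pfp,
      deps = list())))
  }

  run_one <- function(j) {
    r <- rules[[j]]
    ctx <- make_ctx(r)
    for (p in r$deps) {
      if (is.null(rule_of(p)) && !file.exists(p)) {
        pr <- match_pattern(ruleset, p)
        if (!is.null(pr)) ensure_pattern_product(p, pr, ctx)
        else tf_stop("missing_rule", "input '%s' of rule '%s' does not exist", p, r$name)
      }
    }
    for (p in r$outputs) dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      r$action(ctx)
      list(ok = TRUE,
           entries = c(new_entries_of(r, ctx$dynamic_deps), ctx$extra_entries),
           seconds = proc.time()[["elapsed"]] - t0, error = NA_character_)
    }, error = function(e) {
      list(ok = FALSE, entries = ctx$extra_entries,
           seconds = proc.time()[["elapsed"]] - t0,
           error = conditionMessage(e))
    })
    res
  }

  absorb <- function(j, res) {
    r <- rules[[j]]
    for (e in res$entries) {
      assign(e$path, list(digest = e$digest, fingerprint = e$fingerprint,
                          deps = e$deps), envir = db)
      assign(e$path, e$digest, envir = digest_cache)
    }
    db_append(db_path, res$entries)
    if (res$ok) {
      log("built    %s (%.2fs)", r$name, res$seconds)
      report[[length(report) + 1L]] <<- new_report_row(r, "built", res$seconds)
    } else {
      log("FAILED   %s: %s", r$name, res$error)
      report[[length(report) + 1L]] <<-
        new_report_row(r, "failed", res$seconds, res$error)
    }
    res$ok
  }

  # --- scheduler -----------------------------------------------------------
  done <- logical(n)      # finished (built or skipped)
  failed_any <- FALSE
  pending <- topo
  first_out <- vapply(rules, function(r) r$outputs[1], "")
  failures <- character()

  deps_done <- function(j) all(vapply(preds[[j]], function(p) done[p], TRUE))

  while (length(pending)) {
    ready <- pending[vapply(pending, deps_done, TRUE)]
    if (!length(ready)) break
    # skip clean rules immediately; collect dirty ready rules for dispatch
    clean <- ready[!dirty[ready]]
    for (j in clean) {
      log("skipped  %s (up to date)", rules[[j]]$name)
      report[[length(report) + 1L]] <- new_report_row(rules[[j]], "skipped-up-to-date")
      done[j] <- TRUE
    }
    pending <- setdiff(pending, clean)
    if (length(clean)) next
    if (failed_any && !keep_going) break
    batch <- ready[tf_order(first_out[ready])]
    batch <- batch[seq_len(min(length(batch), max(1L, jobs)))]
    if (jobs > 1L && length(batch) > 1L) {
      procs <- lapply(batch, function(j) parallel::mcparallel(run_one(j)))
      results <- parallel::mccollect(procs, wait = TRUE)
      for (k in seq_along(batch)) {
        j <- batch[[k]]
        res <- results[[k]]
        if (!is.list(res) || is.null(res$ok))
          res <- list(ok = FALSE, entries = list(), seconds = NA_real_,
                      error = paste("worker crashed:", paste(res, collapse = " ")))
        ok <- absorb(j, res)
        done[j] <- TRUE
        if (!ok) { failed_any <- TRUE; failures <- c(failures, rules[[j]]$name) }
      }
    } else {
      j <- batch[[1]]
      ok <- absorb(j, run_one(j))
      done[j] <- TRUE
      if (!ok) { failed_any <- TRUE; failures <- c(failures, rules[[j]]$name) }
    }
    pending <- setdiff(pending, batch)
  }

  for (j in pending) {
    report[[length(report) + 1L]] <- new_report_row(rules[[j]], "not-run")
  }

  rep <- structure(
    list(rows = do.call(rbind, report) %||%
           data.frame(rule = character(), output = character(),
                      status = character(), seconds = numeric(),
                      error = character(), stringsAsFactors = FALSE),
         targets = targets, failed = failed_any, failures = failures,
         digest_algorithm = "sha1/base32"),
    class = "tf_report")
  report_path <- file.path(workdir, "last-report.json")
  try(write_report_json(rep, report_path), silent = TRUE)
  if (failed_any)
    tf_stop("build_failed", "build failed in rule(s): %s\n%s",
            paste(failures, collapse = ", "),
            paste(utils::capture.output(print(rep)), collapse = "\n"))
  rep
}

#' @export
print.tf_report <- function(x, ...) {
  tab <- table(factor(x$rows$status,
                      levels = c("built", "skipped-up-to-date", "failed", "not-run")))
  cat(sprintf("<build report> %d rules: %d built, %d up-to-date, %d failed, %d not run\n",
              nrow(x$rows), tab[["built"]], tab[["skipped-up-to-date"]],
              tab[["failed"]], tab[["not-run"]]))
  if (nrow(x$rows)) {
    for (i in seq_len(nrow(x$rows))) {
      r <- x$rows[i, ]
      cat(sprintf("  %-20s %-18s %s\n", substr(r$rule, 1, 20), r$status,
                  if (!is.na(r$seconds)) sprintf("%.2fs", r$seconds) else ""))
    }
  }
  invisible(x)
}

#' Write a build report as JSON
#'
#' @param report A `tf_report` from [build()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(digest_algorithm = report$digest_algorithm,
         failed = report$failed, targets = report$targets,
         rules = report$rows),
    path, auto_unbox = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}

#' Count of rules with a given status
#'
#' Convenience accessor for reports: how many rules were actually rebuilt,
#' skipped as up to date, or failed.
#'
#' @param report A `tf_report`.
#' @param status One of `"built"`, `"skipped-up-to-date"`, `"failed"`,
#'   `"not-run"`.
#' @return Integer count.
#' @export
rules_with_status <- function(report, status = "built") {
  sum(report$rows$status == status)
}
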