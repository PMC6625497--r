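---
title: "Tag-checked workflows: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-checked workflows: model, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bioinformatics analyses are long chains of programs coupled by intermediate
files. Two failure modes dominate in practice: a stage is handed a file in
the wrong format or state (unsorted input to a duplicate marker, a VCF where
a BAM was expected), discovered only hours into a run; and ad-hoc naming of
intermediates, which breaks resumability and invites stale-file reuse.
typedflow addresses both. Workflows are written as forward compositions of
*stages*; every stage declares, as *tags*, what it requires of its input and
what it guarantees about its output; the whole pipeline is checked against a
tag algebra **before anything executes**; and intermediates are named by
content hashes and built by an incremental engine with a persistent digest
database.

The checking is deliberately static in spirit: tags are asserted and
verified at the workflow-graph level only, never against file bytes, so
validation is free at run time. The toy builders shipped with the package do
verify their input dialects -- not as part of the model, but precisely so
that the model's guarantee ("pipelines that validate never feed a stage the
wrong kind of file") is empirically testable.

## The model

A pipeline expression is one of

* **Source** -- user files plus asserted tags (possibly valued, e.g. the
  reference genome association);
* **Compose** -- an upstream expression piped into a stage
  (`e %>>% stage`, left-associative);
* **AllOf** -- a bundle of expressions treated as one multi-path input.

Tags live in a *tag algebra*: declared identifiers, optionally carrying a
file extension (format tags), a value, or the *propagating* property, plus
implication rules. The effective tags of a node are

* Source: the closure of its declared tags;
* Compose: the closure of the stage's output tags, plus every propagating
  tag held upstream, plus the stage's *transient* tags that held upstream;
* AllOf: the intersection of the members' tag sets.

Closure is the least fixpoint of the implication relation -- a genuine
closure operator (extensive, monotone, idempotent), which the tests verify
on random algebras against a brute-force reachability oracle. A typical
implication: deduplicated files count as duplicate-marked, so a caller
requiring marked duplicates accepts deduplicated input.

Intersection semantics for bundles is a design choice the source material
leaves open: a bundle promises only what *every* member can promise, the
sound, under-promising option. Likewise, a valued tag queried through a
bundle whose members disagree is an error rather than last-wins -- a silent
reference-genome mix-up is exactly the bug class this package exists to
prevent. When a valued tag is set at several points along one chain, the
nearest upstream setting wins (shadowing is permitted and documented).

The EDAM ontology connects flat tags to a format hierarchy: attaching a term
to a tag installs implications along the is-a ancestor chain, so a stage
requiring the generic FASTQ format accepts anything tagged with a FASTQ
sub-format. The package bundles a ~52-term subset of the format/data axes as
a plain tabular fixture; the loader verifies acyclicity and parent
existence. Full-release OBO ingestion and non-is-a axes are out of scope.

## Validation, naming, compilation

`validate()` is the single gate, run over the whole expression: every
Compose node's required tags must be contained in the upstream effective
tags. Violations are *collected exhaustively* (better diagnostics than
fail-fast), along with managed-path collisions and bundle value conflicts.
Composition itself never throws on a tag mismatch -- you can build a wrong
pipeline, mirroring how one can write ill-typed code; checking happens at
the compile step, and `compile()` refuses outright while any error
diagnostic is outstanding. "Well-tagged or no rules" is the library's
contract.

Managed intermediates are named
`<workdir>/<digest>.<stage>.<ext>`, where the digest is SHA-1 (base32,
32 characters) over the upstream *relative* path list, the stage name and
the sorted semantic parameters. Three consequences, all tested:

* renaming or moving the work directory changes only the prefix -- the
  digest chain is location-independent;
* `threads` and resource requests are excluded -- changing parallelism
  never invalidates outputs;
* two configurations of the same stage cannot collide, because parameters
  are folded in. Hashing only input paths would let them collide; folding
  in stage identity and parameters closes that gap, and also makes the
  compiler's deduplication key (the output-path sequence) imply action
  identity.

The extension comes from the stage's first output tag, which must carry a
registered extension -- checked at stage-definition time by
`define_stage()`, the factory that replaces per-stage boilerplate.

Compilation is a post-order traversal emitting one rule per Compose node,
with a seen-set keyed on output-path sequences: pipelines sharing a
preprocessing prefix compile the prefix once, within and across calls when
a `compile_state()` is shared. `out()` appends copy rules (symlinks behind
an option) so managed digest files remain valid for the database.

## The build engine

Rules are scheduled topologically from the requested targets. A rule reruns
iff any output is missing or its content digest changed, its fingerprint
(identity + static dependency list) changed, a recorded dependency's digest
changed, or a dependency's rule reran in this build. Freshness is judged by
content digests, never mtimes -- robust on copy-restored workspaces.
Rerun-propagation (rather than stopping when a rebuilt dependency happens to
reproduce identical bytes) keeps the semantics simple and predictable: the
rebuilt set after perturbing any file equals that file's producer plus its
DAG descendants, which the tests verify against an independent reachability
oracle on randomized graphs up to 30 nodes.

State is a JSON-lines database, appended after every completed rule and
last-entry-wins on load; a corrupt line is skipped, degrading to a rebuild
-- never to wrong reuse. This yields re-entrancy: an interrupted or failed
build resumes from the last completed rule. Failure policy defaults to
stop-dispatching-and-drain; `keep_going` flips it.

Ready rules are dispatched in lexicographic order of first output (stable
reports) and may run concurrently up to `jobs` via forked workers; results
are identical to a serial build, checked byte-for-byte. Dynamic
dependencies are declared mid-action with `ctx$need()`: pattern rules
(make-style, one `*` stem) build side products such as index files on
demand -- explicit rules take precedence, two matching patterns are an
ambiguity error. A dynamic need of an explicit rule's output requires it to
be already scheduled via static dependencies; the fully general oracle
rules of industrial build tools are out of scope.

## Executors

Builders never spawn processes directly; they call `run_command()` on the
executor they receive. The local executor passes the token vector as argv,
without shell interpretation. The script executor writes each command into
a POSIX job script with Torque-style headers
(`#PBS -l nodes=1:ppn=<threads>,mem=<mem>mb[,walltime=hh:mm:ss]`,
optional `#PBS -q`). In `dry` mode (the default) the script is executed
locally right after being written, exercising the whole generation path
with no scheduler; in `submit` mode the configured command is invoked and
completion is detected by polling a sentinel file the script touches --
a deliberate choice, since queue-polling protocols are scheduler-specific.
Other header dialects are a single substitution point away but out of
scope. The tests require the two executors to be observationally identical
on the full toy suite.

## What the synthetic data emulates -- and what it does not

`gen_reads()` writes a reference of uniform-random contigs (default 5 x
600 bp), plants point variants spaced at least a read length apart, and
samples error-free reads (default 120-200 x 60 bp, ~4x coverage) from the
mutated copy; a fraction (default 10%) are exact in-place duplicates. Each
variant gets three supporting reads at fixed distinct offsets, so recovery
is a deterministic property of a correct pipeline, not a statistical
accident: the align/sort/mark-duplicates/call chain must recover the
planted variants *exactly*, across seeds. Defaults were chosen once as
realistic toy-scale study conditions: large enough that sorting, duplicate
marking and pileup support thresholds are all exercised (>=2 supporting
reads, guaranteed 3), small enough that a full pipeline builds in a couple
of seconds.

The generator deliberately omits: sequencing error, indels and structural
variants, reverse-strand reads, quality scores, paired-end structure, and
non-uniform genome composition. The toy aligner places reads by exact
half-seed match with a small mismatch allowance (enough for one planted
variant per read, guaranteed by the variant spacing); the toy caller is a
bare pileup. Passing tests therefore demonstrate properties of the
*workflow machinery* -- validation soundness, minimal rebuilds, scatter--
gather equivalence, executor transparency -- on faithfully shaped data
flows; they say nothing about the accuracy of real aligners or callers,
which the framework intentionally does not model (tags are trusted, not
verified, on real tools).

Duplicate ground truth is positional: the expected flag count is the number
of records after the first at each (contig, start), computed independently
by the generator and compared with the duplicate marker's output.

## Numerical and procedural choices

* Digests: SHA-1, base32 lowercase, 32 characters (20 bytes encode to
  exactly 32 characters); fixed so test fixtures are reproducible, pluggable
  behind one function. The naming test pins a value computed independently
  with Python's hashlib/base64.
* All ordering that affects output bytes uses locale-independent radix
  sorts (tag sets, scheduler tie-breaks, gathered line sorting).
* Degenerate inputs: empty source path lists, empty bundles, zero-tag
  closures, empty ontology files, arity mismatches in `out()` are all
  defined errors or fixed points, each with a test.
* Scatter--gather: shard order is the parent's output-path index order. The
  gather used for equivalence checking is `concat(sort_lines = TRUE)`
  (order-insensitive); per-query top-m extraction makes the sharded and
  unsharded runs byte-identical for any shard count.
* Problem sizes in the delivered suites: 200 sampled pipelines for
  validation soundness, 50 (tests) / 30 (acceptance script) random DAGs for
  rebuild minimality, shard counts {1, 2, 5}, 10 seeds for end-to-end
  recovery -- the package's own choice of study size, comfortably past the
  point where each property's failure modes would show.

## Known limitations

Output arity is not checked statically: a stage expecting one input can be
composed after a multi-output node and fails only at validation or run
time if tags happen to match -- typed-length path lists are explicitly not
attempted. Dynamic-arity stages are expressed as two static builds with
host-language logic between (the supported idiom; see the two-phase
example in the README). Live scheduler submission, CWL/WDL export,
containers and remote caching are out of scope. Tag assertions on real
tools are trusted, not verified; the defensive checking in the toy pack is
a property of the test harness, not of the framework.
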