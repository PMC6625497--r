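Package: typedflow
Title: Tag-Checked Bioinformatics Workflows with an Incremental Build Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An embedded domain-specific language for composing bioinformatics
    workflows as forward-chained stages carrying declarative tags (file
    formats and metadata such as sortedness or duplicate marking). Whole
    pipelines are validated against a tag algebra -- including implication
    rules and an EDAM ontology hierarchy -- before any stage runs, so
    incompatible stage orderings are rejected up front. Intermediate files
    are named by content hashes and built by a make-like incremental engine
    with a persistent digest database, giving deduplication across
    pipelines, resumable builds, and parallel execution. Commands run
    through a pluggable executor that either spawns processes locally or
    emits Torque-style cluster job scripts. A self-contained toy stage pack
    (aligner, sorter, duplicate marker, variant caller, k-mer search) and a
    synthetic read generator make every workflow shape runnable and
    checkable without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
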