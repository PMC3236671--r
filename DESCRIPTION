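Package: cifio
Title: Reading, Writing and Validation of Crystallographic Information Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolbox for the Crystallographic Information
    File (CIF 1.1) format. Provides a tokenizer and parser with a strict
    (fail-fast) mode and a lenient mode that recovers from the syntax
    errors most commonly found in archived CIFs, recording every finding
    as a classified diagnostic; an ordered block/loop object model with
    column-stored loops and loop-name inference; a writer producing
    syntactically valid CIF with per-value quoting and a fast
    preformatted-loop path; validation of documents against DDL1 and DDL2
    data dictionaries through a replaceable error handler; and
    interconversion with crystallographic objects (unit cells, space-group
    symmetry operations, atomic sites, reflection data) including
    metric-tensor geometry with first-order standard-uncertainty
    propagation. A programmatic fixture generator produces well-formed and
    deliberately malformed test inputs plus toy dictionaries, and a small
    command-line front end exposes lint, validate and convert workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
Collate:
    'AllClasses.R'
    'diagnostics.R'
    'numbers.R'
    'tokenize.R'
    'parse.R'
    'model.R'
    'write.R'
    'dictionary.R'
    'validate.R'
    'symmetry.R'
    'cell.R'
    'xtal.R'
    'geometry.R'
    'fixtures.R'
    'cli.R'
RoxygenNote: 7.3.3
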