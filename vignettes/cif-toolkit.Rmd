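---
title: "Parsing, validating and interconverting Crystallographic Information Files"
author: "cifio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing, validating and interconverting Crystallographic Information Files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifio)
```

## The problem

The Crystallographic Information File (CIF 1.1) is the standard text format
for archiving small-molecule crystal structures and, increasingly, their
reflection data; large public repositories hold hundreds of thousands of
such files, deposited by many programs over several decades. Two practical
facts shape any serious CIF tool. First, the format has a small, precise
grammar — data blocks, tag–value items, `loop_` tables, quoted strings that
may not cross a line ending, semicolon-delimited multi-line text fields.
Second, a substantial fraction of archived files violate that grammar in a
small number of recurring ways: dropped quotes, hand-edited loops with a
value missing, non-ASCII author names pasted in from word processors,
unquoted values beginning with `[`, forbidden `global_` frames left in by
library formats. A parser that only rejects is useless for curation; a
parser that silently accepts everything corrupts archives further.

`cifio` therefore implements two parsing modes around one grammar:

* **strict** — the first error-severity diagnostic raises a classified R
  condition (`cifSyntaxError`) carrying the offending location and class;
* **lenient** — parsing continues after a *documented* recovery action per
  error class, and every recovery is recorded as a diagnostic row with
  `recovered = TRUE`, so nothing is hidden.

A clean file parses identically in both modes; strict-mode acceptance is a
strict subset of lenient acceptance.

## The error taxonomy and its recoveries

Diagnostics carry an integer `class` from a twelve-entry taxonomy of the
syntax errors most commonly found in archived CIFs
(`cifErrorClasses()`). The lenient recovery per class:

| class | defect | recovery |
|---|---|---|
| 1, 2 | missing closing quote (2: string contains whitespace) | string closed at end of line |
| 3 | non-comment junk before the first `data_` heading | skipped up to the first heading |
| 4 | unterminated semicolon text field | rest of input consumed; the partial model built so far is returned with an unrecoverable diagnostic |
| 5 | more than one value for a tag | first value kept, extras discarded |
| 6 | tag with no value | tag dropped |
| 7 | items before any heading | placed in a synthetic block with an empty name |
| 8 | heading containing whitespace/illegal characters | heading accepted verbatim |
| 9, 10 | non-ASCII bytes; unquoted value starting `[` | offending tag–value pair discarded |
| 11 | loop value count not a multiple of the tag count | entire loop rejected; the diagnostic names the loop, since no single line is at fault |
| 12 | `global_` frame | items become a fallback lookup scope if permitted, else discarded |

Decisions worth recording:

* **Class 5** could equally keep the last value; we keep the *first* and
  discard the extras, reading the extras as the invalid tokens.
* **Class 8** cannot be seen by the lexer (whitespace has already split the
  intended heading into separate tokens), so it is detected parser-side as
  bare values immediately following a heading and re-attached verbatim.
* **Classes 9/10 inside a loop**: discarding a "tag–value pair" is
  meaningless for a looped value, so the offending *row* is dropped,
  keeping all columns the same length.
* **Class 12**: when `permitGlobalBlocks = TRUE` (needed for monomer-library
  style files), lookups in a block consult the block first, then the most
  recent preceding `global_` frame. The global items are never serialized
  as part of the block, so writing does not launder inherited values into
  ownership.
* **Unterminated text field (class 4)**: whether a lenient parser should
  return partial results here is genuinely open; we surface everything
  parsed before the failure plus the unrecoverable diagnostic, on the view
  that curation workflows want to see as much as possible.
* **Duplicate data names or block codes** are class-0 errors: strict mode
  raises, lenient mode keeps the last occurrence.
* The 2048-character line limit is a warning, never an error — real
  archived files exceed it.
* Accepted bytes are ASCII 9, 10, 13, 32–126; anything else is class 9.
  Input bytes are decoded as latin1 (one byte = one character) so an
  offending byte can be located exactly.

## The model and the writer

A `CifDocument` is an ordered, case-insensitively unique mapping of block
codes to `CifBlock`s; a block holds scalar items, `CifLoop`s (values stored
by column) and nested save frames (needed for DDL dictionaries). Values are
**raw strings**: numeric interpretation (`parseCifNumber()`) is on demand
and never destructive, so `0.0250(10)` survives a round trip untouched.
A value such as `10.232(3)` yields value 10.232 with standard uncertainty
0.003 — the parenthesized digits scale to the last decimal place of the
mantissa.

The loop name is the longest common *prefix* of the member names trimmed
back to the last separator — underscore for DDL1-style names, point for
DDL2/mmCIF-style names (detected by the presence of a point). We read the
conventional "longest common substring" phrasing as a prefix rule: a
non-leading common substring could not serve as a category name. When no
separator beyond the leading underscore is reached, the first name is used
whole.

The writer decides quoting per value: plain tokens pass through; values
with whitespace or a forbidden first character (`' " _ # $ [ ] ;`) or
matching a reserved word (`data_...`, `loop_`, `save_...`, `global_`,
`stop_`) are quoted, preferring single quotes; a value containing a newline
or both quote styles unquotably becomes a semicolon text field. Output
always re-parses strictly to the same model. Two formatting escapes exist:
`cifWriteOptions(alignColumns=, indentLoopValues=, dataNameFieldWidth=)`
for appearance, and per-loop `sprintf` row templates which bypass the
per-value quoting checks entirely — the fast path for large reflection
loops, where the caller takes responsibility for safety. Byte-identical
output with any other CIF writer is explicitly not a goal; re-parse
equality is.

Three values are not representable and are refused rather than corrupted: a
value with a line starting `;` (cannot be text-fielded), leading/trailing
newlines (not preserved by a text field), and non-ASCII content. A zero-row
loop, while valid in the model, is not serialized unambiguously by CIF 1.1
(the following item would be read as part of the header), so round-trip
identity is guaranteed only for loops with at least one row and the fixture
generator emits 1+ rows.

## Dictionary validation

`loadDictionary()` accepts a path, literal CIF text, a parsed document, or
a register key resolved through a pluggable resolver
(`options(cifio.dictionaryResolver = ...)`); the network path is off by
default so everything works offline. DDL1 dictionaries carry one
definition per data block (`_name`, `_type`, `_enumeration`,
`_enumeration_range`, `_list`, `_list_reference`, `_type_conditions`);
DDL2 dictionaries carry save frames (`_item.name`, `_item_type.code` with
the dictionary's own `_item_type_list.construct` regexes,
`_item_enumeration.value`, `_item_range.*`, `_item_linked.*`,
`_item_aliases.*`). The version is auto-detected from the shape.
Attributes outside this subset are ignored silently — the subset covers
the checks a validation report implies, not the whole of either DDL.

`validateCif()` routes **every** finding through a replaceable handler
before adding it to the report, so applications can escalate or filter;
the default handler accumulates silently. Severities are a package choice
the DDLs do not fix: unknown name = warning; type, enumeration, range,
su-where-forbidden, list-context and missing-parent violations = errors.
`?` and `.` are always accepted (unknown/inapplicable). For DDL1, a
standard uncertainty is permitted only where `_type_conditions` says
`esd`/`su`; for DDL2 the parenthesis convention is not policed (mmCIF
expresses uncertainties in separate items), a documented asymmetry.

## Crystallographic objects

`extractCrystalSymmetry()` / `extractCrystalStructure()` read the cell
(with su), symmetry and `_atom_site` loop under both core-CIF and
mmCIF-pointed names; `structureAsCif()` emits them back, re-attaching
uncertainties in parenthesis notation. Symmetry operations are
rotation+translation pairs; xyz triplets such as `-x,y+1/2,-z+1/2` parse by
evaluating the coordinate expressions at unit vectors (translations must be
twelfths with denominator 1, 2, 3, 4 or 6) and render canonically, with
`parse(render(op)) == op` exact. `symmetryOpsAsLoop()` refuses sets that
are not closed under composition modulo lattice translations. The bundled
group table is deliberately tiny — P1, P-1, P2\_1/c — enough to exercise
identity, inversion and screw/glide translation arithmetic; full
Hermann–Mauguin interpretation is out of scope, and an unrecognized symbol
falls back to identity with a warning.

Reflection loops (`_refln`) extract into a `ReflectionSet`: integer Miller
indices plus one named column per recognized family (measured/calculated F
and F²), sigmas attached to their parents by name. `?` becomes `NA` —
missing, never zero. Rows with non-integer or (0,0,0) indices are dropped
with a warning.

Geometry works directly in fractional coordinates through the metric
tensor `G`: `d = sqrt(dx' G dx)`, angles from the `G` inner product.
Standard uncertainties are propagated to first order: the analytic
gradient with respect to the six or nine fractional coordinates is
sandwiched with the supplied covariance, and the six cell parameters
contribute independently through their su values (coordinate–cell
cross-correlation is not modelled; nor are torsions — both out of scope).
The tests hold this route against an independent Cartesian-basis oracle to
1e-10 Å / 1e-8° over 1000 random triclinic cells, and the analytic su
against central finite differences to 1e-6 relative.

## What the generators emulate — and what they do not

`makeRandomDocument()` draws items and loops whose values cover every
quoting style the writer supports (plain, whitespace, leading bracket,
embedded single/double/both quotes, multi-line, underscore-leading,
`?`/`.`/empty); `makeMalformed()` produces one minimal exemplar per error
class; `makeStructureFixture()` draws cells per crystal system (lengths
5–15 Å; triclinic angles 80–100°, monoclinic β 95–110°), coordinates
rounded to 4 decimals with su of a few parts in 10⁻⁴, U values in
0.01–0.08 Å² — magnitudes typical of routine small-molecule work;
`makeReflectionFixture()` draws unique indices in a ±5 cube with
F²-with-sigma columns and ~5% missing measurements. All are pure functions
of their seed.

These fixtures are *minimal* exemplars: real archived files combine several
defects at once, use vendor-specific item names, and reach thousands of
lines per loop. Passing the suite therefore demonstrates the grammar,
recovery, round-trip and numeric machinery on controlled input; it does not
certify behaviour on any particular archive. Corpus-scale throughput and
file counts are likewise outside what a test suite of this size can state.

## Problem sizes and numerical choices

The shipped test-and-acceptance runs use 200 random documents for the
round-trip property, 500 name sets for loop-name inference, 1000 random
triclinic cells for the geometry oracle, 1000 generated `value(su)` strings
for the numeric convention, and 25+25 structure/reflection round trips —
sizes at which every property has either failed quickly or holds with wide
margin, while the whole suite runs in well under a minute. Tolerances:
geometry oracle agreement 1e-10 Å (observed ~1e-15), su-vs-finite-difference
1e-6 relative (observed ~1e-10), exact string identity everywhere a
round-trip is claimed. Tie-breaks worth noting: `formatNumberSu()` chooses
the smallest number of decimals that makes the su an integer count of the
last place; symmetry translations snap to a twelfths grid with tolerance
1e-6; angle propagation guards `sin θ` away from zero, and coincident
sites raise rather than return NaN.

## Limitations

CIF 2.0 (UTF-8, triple-quoted strings, lists/tables), CBF/imgCIF binary
sections, STAR nested loops, DDLm/dREL, structure-factor calculation,
scattering factors, general space-group symbol interpretation and the
restraints dictionary are all out of scope. Comments are discarded on
parsing (`keepComments` retains them in the token stream only), so round
trips are modulo comments and whitespace.
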