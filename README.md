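# cifio — reading, writing and validation of Crystallographic Information Files

`cifio` is an R toolbox for the CIF 1.1 format — the standard text format
in which small-molecule crystal structures and their reflection data are
archived and exchanged. It is aimed at crystallographers and database
curators who need to read files that are *almost* valid, at developers who
need a faithful in-memory CIF model with a guaranteed-valid writer, and at
anyone extracting unit cells, symmetry operations, atomic sites or Miller
arrays from CIFs into R.

The package provides:

* **A tokenizer and parser with two modes.** Strict mode raises a
  classified condition at the first grammar violation. Lenient mode
  recovers from the twelve syntax-error classes most commonly found in
  archived CIFs (missing quotes, junk preambles, unterminated semicolon
  text fields, extra/missing values, missing or garbled `data_` headings,
  non-ASCII bytes, unquoted leading `[`, wrong loop value counts,
  `global_` frames) and records every recovery as a diagnostic with an
  error-class code and source location. A loop whose value count is not an
  exact multiple of its tag count is rejected whole, with a loop-scoped
  diagnostic — no single line is at fault.
* **An ordered block/loop model.** Documents map block codes to blocks;
  blocks hold scalar items, column-stored loops and save frames; each data
  name occurs at most once per block (case-insensitive); values are raw
  strings, with the CIF numeric convention (`10.232(3)` → value 10.232,
  standard uncertainty 0.003) interpreted on demand by `parseCifNumber()`.
  Loop names are inferred as the longest common prefix of the member names
  trimmed at the last underscore (DDL1) or point (DDL2/mmCIF) separator.
* **A writer whose output always re-parses.** Quoting is decided per value
  (plain / `'…'` / `"…"` / semicolon text field); `parse(write(x))` equals
  `x` on the model. Per-loop `sprintf` row templates skip the per-value
  quoting checks — the fast path for large reflection loops.
* **DDL1/DDL2 dictionary validation** with a replaceable error handler:
  type, enumeration, range, standard-uncertainty, list-context and
  linked-parent checks; unknown names warn.
* **Crystallographic interconversion.** Extraction and emission of unit
  cells (with su), space-group symmetry-operation loops (closure-checked;
  xyz triplets such as `-x,y+1/2,-z+1/2` parse and render exactly), atomic
  sites with isotropic/anisotropic displacement parameters, and fcf-style
  reflection data where `?` means *missing*, never zero. Geometry is
  computed through the metric tensor, `d = sqrt(Δx' G Δx)`, with optional
  first-order propagation of standard uncertainties from a coordinate
  covariance matrix plus the cell-parameter su.
* **Fixture generators and a CLI.** Deterministic generators for random
  well-formed documents, one malformed exemplar per error class, toy
  dictionaries, structures (P1, P-1, P2₁/c) and reflection sets; `lint`,
  `validate`, `convert` and `fixtures` workflows via exported functions or
  the `inst/scripts/cif_tool.R` wrapper.

## Worked example

```r
library(cifio)

txt <- "data_quartz
_cell_length_a 4.9137(2)
_cell_length_b 4.9137(2)
_cell_length_c 5.4047(3)
_cell_angle_alpha 90
_cell_angle_beta 90
_cell_angle_gamma 120
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_occupancy
_atom_site_U_iso_or_equiv
Si1 Si 0.4697(1) 0.0000 0.0000 1 0.0079(2)
O1 O 0.4133(3) 0.2672(2) 0.1188(1) 1 0.0146(4)
"
doc <- parseCif(txt, cifParseOptions(strict = TRUE))
st  <- extractCrystalStructure(doc[["quartz"]])
st
#> CrystalStructure: 2 site(s), 1 symmetry operation(s)
#> UnitCell: a=4.9137 b=4.9137 c=5.4047  alpha=90 beta=90 gamma=120  V=113.011 A^3

siteDistance(st, 1, 2)$value
#> [1] 1.605174
```

The cell is hexagonal (γ = 120°), so the 1.6052 Å Si–O separation comes
out of the metric tensor, not a naive Euclidean difference of fractional
coordinates; the `(2)`/`(3)` suffixes were parsed into standard
uncertainties on the cell and coordinates (`st@cell@su`,
`st@sites$suX`, ...).

A mangled loop is diagnosed rather than mis-read:

```r
bad <- "data_b\nloop_\n_refln_index_h _refln_index_k\n1 0 2\n"
cifDiagnostics(parseCif(bad))[, c("line", "severity", "class", "message")]
#>   line severity class                                                message
#> 1    2    error    11 wrong number of values (3) for loop _refln_index w...
```

In strict mode the same input raises a `cifSyntaxError` carrying that
diagnostic.

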