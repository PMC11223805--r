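---
title: "Drawing human pedigree charts from PED files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing human pedigree charts from PED files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedchart)
```

## The problem

A pedigree chart communicates family structure and disease segregation at
a glance, but drawing one by the accepted nomenclature conventions is a
constraint-satisfaction problem: fathers should sit on the left of their
partners whenever possible, children should be centred under their
parents and run left-to-right in a fixed order, every individual must sit
exactly on its generation row, and none of the connector lines — partner
lines, sibship buses, drop lines — may cross or run through a symbol.
Consanguinity makes this genuinely hard, because a mating between
relatives closes a *loop* in the family graph that the drawing must close
without crossings.

The family structure itself is captured in the decades-old PED
(pre-makeped) format: one row per person with family ID, individual ID,
father ID, mother ID, sex (1/2/0) and phenotype (1/2, with 0 or −9 as
missing). PED cannot express clinically relevant facts such as deceased
persons, miscarriages or proband status, so `pedchart` reads and writes
an optional 7th column holding a comma-separated keyword list
(`deceased`, `miscarriage`, `proband`, `consultand`,
`consanguineous_partner`; unknown keywords are carried through verbatim).
Export back to strict 6-column PED simply drops that column, which keeps
the files interoperable with linkage and association tools that expect
plain PED.

## The model of a family

A `pedigree` holds the individuals, the *unions* (one per distinct
father–mother pair, each with its children in natural ID order), and the
founder set. Natural ID order — digit runs compared numerically,
case-insensitive elsewhere — is used everywhere a deterministic order is
needed, because human-assigned IDs like `C1 … C10` are meant to be read
that way.

Validation enforces the facts that make a pedigree drawable at all:

* nobody is their own ancestor (cycles of any length are errors, found by
  iterative pruning of the parent relation);
* every referenced father is male and every mother female; unknown-sex
  parents are rejected because the PED father/mother columns force sexed
  parents;
* a miscarriage has no descendants;
* partners can share one generation row and every child sits exactly one
  row below its parents. A mating that forces one person onto two rows —
  an uncle marrying his niece, or any ancestor–descendant union — is
  reported as a generation conflict and refused, mirroring the
  generation-spanning limitation of this family of chart tools;
* nobody has more than two partners, since the drawing places at most one
  spouse on each side of a symbol.

A parent that is referenced but has no row of its own is repaired into an
inferred founder with a warning rather than an error, because hand-edited
PED files do this constantly. Similarly, a row with exactly one known
parent gets an inferred placeholder partner (`_p1`, `_p2`, …) of the
missing sex; placeholders are collapsed back to `0` on export, so round
trips are lossless. Children sharing the same single known parent share
one placeholder, which keeps the couple structure minimal and the
placeholder numbering independent of row order.

Consanguinity is detected automatically: a union is consanguineous when
the partners share at least one ancestor inside the pedigree, or when one
is an ancestor of the other (both cases are treated alike — the chart
draws the same double line either way). Because the exact structure of a
consanguineous family is often unknown in clinical practice, the manual
`consanguineous_partner` annotation asserts relatedness even when the
shared ancestors are absent from the chart; an asserted union reports
`"asserted"` in preference to `"auto"` but renders identically.

Interactive-style edits (`add_child`, `add_partner`, `add_parents`,
`remove_individual`, `set_sex`, `set_phenotype`, `set_annotation`,
`rename_individual`) all rebuild and re-validate before returning, so no
sequence of edits can produce an invalid pedigree: an edit either returns
a clean pedigree or raises. Two constraints deserve mention: the sex of a
current parent cannot be changed, and a miscarriage can never acquire
children. Removing a parent whose children remain substitutes an
inferred placeholder instead of cascading deletions.

## The two-phase layout algorithm

**Indexing.** Generation numbers are propagated over the family graph:
partner edges carry offset 0, parent→child edges offset +1. Propagation
revisits nodes until a fixed point (bounded by `max_iterations` sweeps);
an inconsistency is exactly a generation conflict and has already been
refused by validation. Each connected component is shifted so its top row
is 0, and each individual then receives an index — its position within
its generation row, with partners adjacent and sibships contiguous.

**Drawing.** X-coordinates are resolved bottom-up over rigid *blocks*.
A block is a partial layout carrying, per generation row, the x-interval
spanned by everything in it (symbols, buses, stems, drop lines). The
block of a person is their symbol alone; if they anchor a union (their
spouse married into the family), it is the couple centred over the
composed blocks of their children, father on the left at `couple_gap`
centre distance. Sibling blocks are packed left-to-right in natural ID
order with a per-row contour separation of `min_gap` edge clearance, so
nothing belonging to different nuclear families can ever collide — that
one invariant is what guarantees "no crossing lines" globally, because
every connector's x-extent is folded into its block's row intervals.

Two structures need dedicated placement rules:

* *Two partners.* The shared person sits between their two spouses, and
  is placed midway between the two sibship groups rather than over either
  mean. This keeps the two bus lines (both one row down, at the same
  height) disjoint: each partner-line midpoint then lies outside the
  other union's child span. The cost is that neither sibship is exactly
  centred — centring is only promised for unions in which both parents
  have a single partner, which is also what the geometry checker tests.
* *Consanguineous loops.* A union whose partners both have recorded
  parents is *mounted* between its two parental blocks. For a
  cousin-type loop the two branch sibships must be adjacent children of
  the common ancestor union, with the father's line hugging the right
  edge of its sibship (last sibling by ID at every level down from the
  divergence) and the mother's line the left edge; the partners then end
  up facing each other across the block gap, the partner line spans the
  gap, and the loop's children hang centred under the couple midpoint,
  pushed-apart blocks making room. The same mechanism lays out a
  marriage that joins two separate founder families. Anything else —
  nested or interlocking loops, loop members away from their sibship
  edge, a loop partner with a second partner — raises a structured
  "unsupported structure" error rather than producing a corrupted
  drawing. Since placement is driven by ID order, a user can often make
  an undrawable file drawable by renumbering siblings so the loop
  partners sit at the facing edges.

`check_layout()` is an independent oracle: it re-derives the unions from
the pedigree and verifies the conventions by direct geometry — row
alignment, father-left (for single-partner unions), centring within
`tolerance`, sibling order, row clearance, pairwise segment crossing
tests and segment-through-symbol tests. `compute_layout()` runs it on its
own output and refuses to return a layout that fails it; `render_svg()`
refuses as well. Keeping the checker free of placement logic is what
makes the layout property-testable.

### Parameters

All lengths are abstract grid units, scaled only at render time
(`px_per_unit`, default 40 px/unit).

| parameter | default | meaning |
|---|---|---|
| `symbol_size` | 0.6 | symbol width/height |
| `min_gap` | 1.0 | minimum horizontal *edge* clearance between non-partner symbols |
| `row_height` | 2.0 | vertical distance between generation rows |
| `couple_gap` | 1.0 | centre distance between partners |
| `double_line_offset` | 0.07 | half-separation of the consanguinity double line |
| `max_iterations` | 100 | bound on indexing sweeps |
| `tolerance` | 0.01 | convergence / geometry-check tolerance |

One reading note: `min_gap` governs clearance between symbols that are
*not* partners. Partners are deliberately closer (centre distance
`couple_gap`, hence edge clearance `couple_gap − symbol_size` = 0.4 by
default) so a couple reads as a unit; `couple_gap` must therefore exceed
`symbol_size`. The bus line sits at 0.6 of the row height below the
parents, far enough from both rows' symbols (half-symbol is 0.3 units)
that buses can never clip a symbol vertically.

A design note: the drawing phase is often described as iterative
adjustment of positions until children and parents agree. This package
instead composes blocks bottom-up with exact centring, which reaches the
same fixed point in one pass and is trivially deterministic and
convergent; the indexing phase keeps the iterative, revisiting character.
The iteration bound and tolerance remain as parameters because the
geometry checker and degenerate-input guards use them.

## Rendering

Symbols follow standardized pedigree nomenclature: squares for males,
circles for females, diamonds for unknown sex, a small triangle for a
miscarriage; filled for affected, outline for unaffected, a centred "?"
for missing phenotype; one diagonal slash for deceased; an arrow with a
"P" for the proband and a bare arrow for the consultand; partner lines
doubled for consanguineous unions. Monochrome only — publication
figures should not rely on colour semantics. Element order is fixed
(lines, then symbols, then marks, then text) and all coordinates are
printed with two decimals, so equal inputs give byte-identical SVG;
tests rely on this. IDs can be suppressed (`show_ids = FALSE`) for
anonymized charts.

PNG export rasterizes the package's own SVG element subset (lines,
rects, circles, polygons, text) onto an R `png()` device whose pixel
size is the SVG size scaled by `dpi/96`. If the R build lacks a PNG
device this fails with an explicit capability error; SVG output never
depends on it.

## The compact pedigree token

`encode_compact()` serializes a complete pedigree — annotations included
— as a short URL-safe string: canonical annotated PED text,
gzip-compressed, prefixed with a one-byte format version and an Adler-32
checksum of the compressed bytes, base64url-encoded. The checksum is
verified *before* decompression, so a corrupted token is rejected up
front and is never handed to the decompressor (a corrupted deflate
stream can otherwise expand unboundedly); the gzip CRC is a second
integrity line. Decoding a token that passes both checks rebuilds and
re-validates the pedigree, so `decode_compact()` either returns a valid
pedigree equal to the encoded one or raises a decode error — never a
silently wrong family. The token format is this package's own; no
compatibility with any external service's link format is attempted.

## The synthetic-pedigree generator

Property tests and the acceptance script need many structurally diverse,
valid families without any external data. `generate_pedigree()` emulates
the shape of clinical human pedigrees: one founding couple; sibships of
1–8 children with truncated-Poisson size (mean 2.5); each child founding
a family with probability 0.6, always with an unrelated founder spouse;
a second partner with probability 0.15; roughly one quarter affected,
5% missing phenotype; auxiliary annotations at 10% per flag, with
miscarriages restricted to unmarried leaves. With probability
`p_consanguineous_loop` one first-cousin loop is planted: two adjacent
married children of the founding couple get an extra last/first child
respectively (male on the left branch, female on the right), who marry;
the loop union always receives children, since a childless union cannot
be expressed in PED at all — when only three generation rows were
requested this adds a fourth for the loop offspring. IDs are assigned in
generation-then-birth order (`P1`, `P2`, …) so natural ID sorting
reproduces the intended left-to-right order, exactly the discipline a
user of an ID-ordered chart tool must follow.

What the generator deliberately does *not* emulate: genetic transmission
(phenotypes are independent draws, not segregating alleles), half-sibling
loops, marriages joining two generated families, and nested loops. A
passing property suite therefore demonstrates correctness for common
human family structures including single cousin loops and double
marriages — it says nothing about the exotic structures the layout
explicitly refuses, which is the intended contract.

`plant_defect()` inverts the generator's guarantees for negative tests:
it injects a two-person cycle, a female father, a miscarriage with
children, or a dangling parent reference into an otherwise valid family.

## Scale of the shipped test evidence

The package's acceptance suite runs 200 generated pedigrees (seeds
0–199, two to five generations, at most ~40 individuals, cousin loops
planted with probability 0.5 and second partners 0.2): PED round trip
and strict-dialect export, zero geometry violations from the independent
checker, consanguinity flags identical to a brute-force ancestor-set
oracle on every union (plus hand-built first-cousin, uncle–niece and
double-first-cousin structures), 100 planted/clean cycle cases and 60
other planted defects, byte-stable reconstruction of the five-person
consanguineous reference family, codec round trips with single-character
corruption probes, and 500 randomized edit sequences that must leave
validation clean after every accepted edit. `scripts/acceptance.R`
recomputes all of these rates from scratch and writes them as JSON.

## Known limitations

* Only one phenotypic trait; no quadrant fills, haplotype bars or
  genotype text.
* At most two partners per person; nested or interlocking consanguineous
  loops, and loops whose members are not at their sibship edges in ID
  order, are refused with a structured error.
* Generation-spanning matings (uncle–niece, ancestor–descendant) are
  validation errors; such unions are still *detected* as consanguineous,
  they just cannot be drawn.
* Positions cannot be adjusted manually; the chart is a pure function of
  the pedigree and the parameters.
* Layout width is minimized greedily per block, not globally; charts are
  compact but not provably minimal-width.
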