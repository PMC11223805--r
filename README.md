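# pedchart

Publication-ready human pedigree charts from standard PED files, in R.

Pedigree charts are the working language of clinical genetics: squares
for males, circles for females, filled symbols for affected individuals,
children centred beneath their parents, a double partner line for
consanguineous unions. Drawing one correctly is a small
constraint-satisfaction problem — fathers left of mothers wherever
possible, siblings left-to-right in ID order, every symbol exactly on its
generation row, and *no* crossing connector lines, even when a
consanguineous mating closes a loop in the family graph. `pedchart` is
for anyone who has family data in PED (pre-makeped) format — the
six-column `family id, individual id, father, mother, sex, phenotype`
layout used by PLINK and linkage software — and wants a
conventions-compliant SVG or PNG chart out of it, with the family logic
checked on the way.

The package provides:

* **PED I/O** — strict 6-column files plus an annotated 7th-column
  dialect for deceased / miscarriage / proband / consultand status and
  manually asserted consanguinity; lossless round trips; multi-family
  files; a compact URL-safe token encoding a complete pedigree.
* **Family-graph validation** — cycles ("persons as their own
  ancestors"), parent-sex conflicts, miscarriages with children,
  generation-spanning matings, dangling parent references
  (auto-repaired with a warning).
* **Automatic consanguinity detection** — a union is flagged when the
  partners share an ancestor in the pedigree (or one is an ancestor of
  the other), or when the user asserts relatedness; either way the chart
  shows a double partner line.
* **A two-phase layout algorithm** — generation/index assignment by
  fixed-point propagation, then bottom-up placement of nuclear-family
  blocks with per-row contours, which guarantees father-left, centred
  children, ID-ordered sibships, minimum clearances and zero line
  crossings; an independent geometry checker (`check_layout`) verifies
  every one of these on every layout.
* **Deterministic rendering** — byte-stable SVG following standardized
  pedigree nomenclature, optional PNG rasterization, optional ID
  suppression.
* **Constrained editing** — add/remove/rename individuals, change
  phenotype or annotations; edits that would break the family logic
  (changing a parent's sex, giving a miscarriage children) are refused,
  and every accepted edit re-validates.
* **A synthetic-pedigree generator** for testing, with defect planting.
* **A CLI** (`ped_cli()`; wrapper script in `inst/cli/pedchart`) with
  `draw`, `validate`, `convert`, `encode`, `decode`, `generate`
  subcommands.

## Worked example

`inst/extdata/example.ped` is a two-family annotated PED file. The
`TRIO` family is a couple with manually asserted consanguinity and three
children:

```r
library(pedchart)

path <- system.file("extdata", "example.ped", package = "pedchart")
fams <- split_families(read_ped(path))
names(fams)
#> [1] "LOOP" "TRIO"

ped <- detect_consanguinity(build_pedigree(fams$TRIO, "TRIO"))
ped
#> Pedigree 'TRIO': 5 individuals, 1 unions (1 consanguineous), 2 founders

lay <- compute_layout(ped)
lay$positions
#>   id   x y generation
#> 1 C1 0.0 2          1
#> 2 C2 1.6 2          1
#> 3 C3 3.2 2          1
#> 4 F1 1.1 0          0
#> 5 M1 2.1 0          0

svg <- render_svg(lay, ped)
svg
#> SVG pedigree chart, 232 x 184 px, 1772 bytes
write_svg(svg, "trio.svg")
```

Reading the numbers: father `F1` (x = 1.1) sits left of mother `M1`
(x = 2.1); the children run `C1 < C2 < C3` left-to-right one generation
row below (y = generation × 2 grid units), and their mean x (1.6) is
exactly the couple midpoint. Because the union is consanguineous the SVG
contains a double partner line (two parallel `line` elements of class
`"partner double"`).

The `LOOP` family contains a first-cousin union; its partners `X1` and
`Y1` end up adjacent across their two parental blocks, with their child
`K1` centred beneath:

```r
loop <- detect_consanguinity(build_pedigree(fams$LOOP, "LOOP"))
loop
#> Pedigree 'LOOP': 9 individuals, 4 unions (1 consanguineous), 4 founders
```

A complete pedigree, annotations included, travels as one URL-safe
token:

```r
tok <- encode_compact(ped)
ped_equal(decode_compact(tok), ped)
#> [1] TRUE
```

From the shell:

```sh
Rscript inst/cli/pedchart draw family.ped -o chart.svg
Rscript inst/cli/pedchart draw family.ped -o chart.png --format png --hide-ids
Rscript inst/cli/pedchart validate family.ped --json
Rscript inst/cli/pedchart generate --seed 7 --generations 4 -o fixture.ped
```

`draw` on a multi-family file lists the available family IDs and asks
for `--family` (or `--all-families` to render one chart per family);
exit codes distinguish usage (1), parse (2), validation (3) and
unsupported-structure (4) failures.

## Limitations

One trait per family; at most two partners per person; single (non-nested)
consanguineous loops whose members sit at the facing edges of their
sibships in ID order; generation-spanning matings (uncle–niece,
ancestor–descendant) are detected as consanguineous but refused for
drawing. Positions cannot be moved manually — the chart is a pure
function of the pedigree, which is what makes it reproducible.
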