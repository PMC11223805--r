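Package: pedchart
Title: Pedigree Chart Layout and Rendering from PED Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses standard PED (pre-makeped) pedigree files, including an
    auxiliary annotation column for deceased, miscarriage, proband and
    consultand status, validates family logic (cycles, parent sex conflicts,
    generation-spanning matings), automatically detects consanguineous
    unions, computes a conventions-compliant chart layout (fathers on the
    left, children centred under their parents, no crossing lines) via a
    two-phase generation-indexing and drawing algorithm, and renders
    publication-ready SVG and PNG pedigree charts using standardized
    pedigree nomenclature. Includes a compact URL-safe serialization of
    complete pedigrees, a synthetic pedigree generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    grDevices,
    graphics,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
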