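Package: glycanKit
Title: Glycan Structure Modelling, GlycoCT Interchange and SNFG Depiction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless toolkit for building, editing and depicting glycan
    structures. Glycans are modelled as rooted trees of monosaccharide,
    substituent and repeating-unit nodes drawn from controlled vocabularies,
    with explicit support for structural fuzziness (undetermined anomericity,
    ring size, absolute configuration and linkage positions). The package
    reads and writes GlycoCT condensed text, lays out structures on an
    integer grid following the bond-angle linkage convention, renders
    SNFG-compliant SVG with dash-coded anomericity, offers quick-mode and
    normal-mode construction interfaces with chemical-validity rules and a
    template library of N-/O-glycan cores and epitopes, and expands fully
    defined structures to atomic graphs for SMILES and molecular-formula
    export. A seeded random-glycan generator supplies reproducible test
    corpora. A command-line front end covers conversion, validation and
    random-structure generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
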