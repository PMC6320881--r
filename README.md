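# glycanKit

Glycans — the branched carbohydrates that decorate proteins and lipids — are
awkward to handle in software: unlike linear biopolymer sequences they form
rooted trees of monosaccharide residues joined by glycosidic linkages, their
structures are routinely only partially determined (unknown linkage
positions, undecided anomeric configuration), and the community draws them
in a symbolic shape-and-colour notation (SNFG) rather than as chemical
diagrams. glycanKit is a headless R toolkit for people who need to build,
edit, exchange, depict and chemically export such structures from code:
glycoinformatics pipeline authors, database maintainers who accept GlycoCT
as an interchange format, and anyone generating publication-quality SNFG
figures without an interactive editor.

## What it provides

* **A glycan tree model** (S4 classes) with controlled vocabularies of
  monosaccharide and substituent types and first-class *fuzziness*:
  UNKNOWN positions, alternative attachment sets like "3 or 4", and
  undetermined anomericity / ring form / absolute configuration. Editing
  operations cover add, delete (subtree prune), update, deep copy/paste
  and repeating units.
* **GlycoCT condensed import/export** with a deterministic canonical
  writer (`parse(write(g))` is isomorphic to `g`, and writing is a
  byte-level fixpoint), including REP blocks for repeating units.
* **Grid layout and SNFG SVG rendering.** The reducing end sits rightmost;
  each linkage's acceptor position sets the bond angle (a 6-linked branch
  rises, a 3-linked branch drops); an occupancy grid resolves collisions so
  symbols never overlap. Anomericity is dash-coded on the bonds:
  solid for β, dashed for α, dotted for undetermined.
* **Quick-mode and normal-mode construction.** Quick mode offers the
  twelve monosaccharides most common in mammalian glycans and asks only
  the linkage anomericity and acceptor position per residue — the donor
  position follows from the residue class (aldoses donate from C1,
  ketoses/ulosonates from C2). Chemical-validity rules (R1–R5) detect
  forbidden combinations; a template library ships the N-glycan core, its
  core-fucosylated variant, O-glycan cores 1–8 and common epitopes.
* **Chemical export** restricted to fully defined structures: expansion to
  an atomic graph by glycosidic condensation (one water lost per linkage),
  molecular formulas, and SMILES strings that external toolkits parse to
  the same formula.
* **A command-line tool** (`inst/cli/glycotool`) for convert / validate /
  template / random, with pipeline-friendly exit codes.

## A worked example

```r
library(glycanKit)

# lactose: Gal-(β1→4)-Glc
g <- createGlycan(monosaccharide("Glc", "beta"))
g <- addMonosaccharide(g, 1, monosaccharide("Gal", "beta"), linkage(1, 4))

cat(writeGlycoCT(g))
#> RES
#> 1b:b-dglc-HEX-1:5
#> 2b:b-dgal-HEX-1:5
#> LIN
#> 1:1o(4+1)2d

molecularFormula(g)
#> [1] "C12H22O11"
atomCount(toMolecularGraph(g))
#> [1] 45
```

The GlycoCT document lists the two residues (`b`-entries: β-D-gluco- and
β-D-galacto-hexopyranose) and one linkage line: residue 1's oxygen at
position 4 bonds residue 2's C1. The formula obeys the condensation law
(2 × C6H12O6 − H2O), and the 45 atoms (hydrogens included) agree with it.
`renderSVG(g)` draws the blue and yellow SNFG circles joined by a solid
(β) bond; `toSMILES(g)` emits a SMILES string that Open Babel and RDKit
parse back to C12H22O11.

Branching follows the angle convention:

```r
b <- createGlycan(monosaccharide("Man", "beta"))
b <- addMonosaccharide(b, 1, monosaccharide("Man", "alpha"), linkage(1, 3))
b <- addMonosaccharide(b, 1, monosaccharide("Man", "alpha"), linkage(1, 6))
layoutCells(layoutGlycan(b))
#>   nodeId col row
#> 1      1   0   0
#> 2      2  -1  -1
#> 3      3  -1   1
```

The 3-arm drops one row, the 6-arm rises one row — the familiar
trimannosyl-core geometry.

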