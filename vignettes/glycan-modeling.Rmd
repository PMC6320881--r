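---
title: "Modelling, exchanging and depicting glycan structures with glycanKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling, exchanging and depicting glycan structures with glycanKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanKit)
```

## The model and its assumptions

A glycan is modelled as a rooted directed tree. The root is the
reducing-end residue (the one with a free anomeric centre); every other
node is reached through exactly one parent edge. Nodes are of three kinds:
`Monosaccharide` (a vocabulary type token plus anomericity, ring form and
absolute configuration), `Substituent` (a childless non-sugar decoration
such as N-acetyl or sulfate), and `RepeatUnit` (an internal glycan
repeated min–max times, treated as a single node in the host tree). Edges
carry a `GlycosidicLinkage`: the donor carbon on the child and a non-empty
set of acceptor positions on the parent. Cyclic glycans are out of scope:
the tree property is enforced by a validity method after every editing
operation.

Partial knowledge is first-class. A position can be UNKNOWN (`NA`), an
acceptor set of size two or more expresses alternative attachment points
("3 or 4"), and anomericity, ring form and configuration each admit an
`undetermined` value. The two fuzziness encodings never mix inside one
linkage (an UNKNOWN never co-occurs with stated alternatives), which keeps
`isFullyDefined()` a simple decidable scan. That predicate — no UNKNOWN,
no alternatives, nothing undetermined, no repeat with UNKNOWN counts — is
the gate for chemical export.

Node ids increase monotonically and are never reused after deletion, so
references held by callers (and tests) stay stable across edits. All
editing operations are functional: they return a new glycan and the id of
the most recent insertion is available as `lastNodeId()`.

### Controlled vocabularies

The monosaccharide table ships 28 types covering the SNFG assignments used
in practice (hexoses, hexosamines, hexuronates, deoxyhexoses, pentoses,
nonulosonates, heptoses, Kdo, Fru), each with its superclass, carbon
count, anomeric carbon, SNFG shape and colour, GlycoCT stereo descriptor,
chain modifications and default configuration/ring. Free-residue formulas
are derived from the superclass composition C~n~H~2n~O~n~ adjusted per
modification (deoxy −O; acid +O −H2; amine +NH −O), so the table cannot
drift out of sync with the chemistry. Substituents carry their attachment
mode — `o` (replaces the hydroxyl hydrogen: methyl, acetyl, sulfate,
phosphate, pyruvate) or `d` (replaces the whole hydroxyl: amino, N-acetyl,
N-glycolyl) — and compositional deltas for both hydroxyl and amine
contexts. Arbitrary tokens are rejected with a vocabulary error.

### Composite residues and canonical form

GlcNAc-like residues are stored decomposed — amino-sugar base type plus an
N-acyl substituent node — mirroring the GlycoCT encoding; fusion to the
single SNFG symbol happens only in the renderer. Because GlycoCT has
exactly one canonical spelling for an amino sugar, the model keeps its
side of the bijection canonical too: attaching `n-acetyl` at a position
where the parent has an amine-bearing variant (position 2 of Glc, 5 of the
neuraminic-acid base) upgrades the parent type (Glc becomes GlcN) with the
acyl group on the nitrogen, and attaching `amino` there performs the
upgrade without creating a node. Without this, `parse(write(g))` could
return a chemically identical but structurally different tree.

## GlycoCT interchange

Only the condensed dialect is supported; UND sections are rejected with an
explicit unsupported-feature error because the model expresses fuzziness
inline. The writer is deterministic: depth-first from the root, substituent
entries before glycosidic children, siblings ordered by smallest stated
acceptor position (UNKNOWN last) with ties broken on an id-independent
subtree serialization key. UNKNOWN positions are written `-1`,
alternatives joined with `|`, line endings are LF (CRLF accepted on
input). Repeating units become REP blocks whose internal linkage names the
acceptor leaf and donor root; unknown repeat bounds are written `-1`. The
same canonical child ordering drives the layout engine, so a structure's
drawing is independent of the insertion order of its branches.

Round-trip fidelity is the module's contract: on the seeded random corpus,
`parse(write(g))` is isomorphic to `g` (checked field-by-field through the
canonical subtree key), writing is a byte-level fixpoint, and
`isFullyDefined` is invariant under the trip. The parser reports the line
number of malformed input and distinguishes parse errors, reference errors
(dangling indices) and the UND rejection by condition class.

## Layout and rendering

The layout assigns integer grid cells: root at (0, 0), children one
column to the left of their parent (columns encode distance from the
reducing end). The preferred row offset comes from the linkage's acceptor
position — 6 rises (+1), 3 drops (−1), 2 and 4 stay level, UNKNOWN and
everything else stay level; for alternative sets the smallest stated
position drives geometry and the renderer prints the full "3/4" label.
The original interface's exact angle table is unpublished, so this map is
this package's own decision anchored to the familiar N-glycan core
geometry. Collisions are resolved by probing rows +1, −1, +2, −2, … in
the same column — deterministic, compact, and sufficient to make
cell assignment injective on every corpus we generate, including
adversarial trees with every attachable carbon occupied.

Rendering emits SVG 1.1 text. Symbol geometry and the ten-colour palette
hex values follow the published SNFG tables and ship as data files.
Anomericity is encoded on edge strokes: β solid, α dash pattern `6,4`,
undetermined dotted `2,3` — chosen to be mutually distinguishable at
default sizes; the renderer also records the anomericity in a
`data-anomericity` attribute so the style law is machine-checkable.
Substituents take no grid cell: they either fuse into the parent's symbol
(GlcN + N-acetyl at C2 → the blue GlcNAc square) or appear as compact text
decorations like `6S`. Repeat units occupy one cell and are drawn
bracketed with their min–max annotation. Symbol sizes and stroke widths
are options (`renderOptions()`) with defaults of 60 px cells and 30 px
symbols; output is byte-deterministic for identical input.

## Quick mode, validation and templates

Quick mode deliberately asks for two chemistry parameters per residue —
the anomericity of the new linkage and the acceptor position — against the
six of normal mode (type = shape+colour, anomericity, ring, configuration,
donor, acceptor). The palette is fixed at the twelve monosaccharides most
common in mammalian glycans: Glc, Gal, Man, GlcNAc, GalNAc, GlcA, IdoA,
Fuc, Xyl, Neu5Ac, Neu5Gc, Kdn; their published inventory is not printed
anywhere, so this list is the package's documented choice of the canonical
mammalian set. Quick-mode defaults are D configuration (L for Fuc and
IdoA, per the types' defaults) and pyranose rings.

The validity rules are data, not exceptions: `validateGlycan()` returns a
violation table (R1 duplicate occupancy, R2 position beyond the carbon
count, R3 donor ≠ anomeric carbon, R4 open-chain residue with α/β
anomericity, R5 substituent on the ring-closure or glycosidically occupied
carbon). Quick mode treats violations as blocking; normal mode leaves them
advisory so experts can hold intermediate states — the same split an
interactive editor makes between novice and expert workflows.

Templates are stored as GlycoCT files and parsed on load (exercising the
parser on every access, and guaranteeing deep copies): the N-glycan core
Man3GlcNAc2, its core-fucosylated variant, O-glycan cores 1–8, and the
epitopes LacNAc, Lewis a/x, sialyl-Lewis x and blood groups A/B/H.

## The random generator

`generateRandomGlycan(seed, nNodes, fuzzProb)` is the corpus generator the
tests and the acceptance script build on. It emulates the combinatorics
that stress this kind of code — branching at arbitrary free positions,
amino sugars with their implied N-acyl groups, occasional O-linked
decorations (15% of insertions), mixed residue classes including sialic
acids and heptoses — while staying chemically conformant by construction:
donors are anomeric carbons, attachment only at carbons that actually
carry a hydroxyl (never deoxy, acid, amine or ring-closure positions), no
double occupancy. `fuzzProb` is the probability that each added residue is
fuzzed through one channel (undetermined anomericity/ring/configuration,
UNKNOWN acceptor, or a two-position alternative set). The generator
restores the session RNG state, so corpora are reproducible and
side-effect-free. Default study conditions used throughout: 500 structures
of sizes 1–40, fuzz 0 and 0.3.

What the generator does **not** emulate: real-world abundance biases (it
samples types uniformly), multi-antennary motifs with biological meaning,
rare substituent chemistry (pyruvate ketals bridging two positions are
simplified to single-position acyl attachment), or cyclic and
UND-annotated structures. Passing tests on this corpus therefore
demonstrate structural and serialization correctness, not biological
realism of the sampled structures.

## Chemical export

Export requires `isFullyDefined()` — the toolkit refuses underdetermined
structures rather than guessing. Each residue is instantiated from its
ring-form template: the carbon chain, the ring oxygen between the
anomeric and closure carbons, hydroxyls at unmodified positions, carboxyls
at acid positions, nothing at deoxy positions, a nitrogen at the amine
position. Glycosidic bonds are formed by condensation with the glycosidic
oxygen taken from the acceptor (the donor's anomeric hydroxyl is the water
leaving group); the choice of side is formula-invariant but fixed for
determinism. One water is lost per glycosidic edge, giving the closed-form
formula Σ residues + Σ substituent deltas − e·H2O, which the test suite
checks against the independent atom-by-atom count of the expanded graph.
Acidic substituents are emitted in their neutral protonated form (pH
modelling is out of scope).

Repeat units are expanded only when their copy count is determinate
(minCount == maxCount); a 2–5 repeat passes `isFullyDefined()` — the
counts are stated — but is compositionally ambiguous, so chemical export
raises the underdetermined error for it. Nested repeats are likewise
refused.

SMILES strings are produced by depth-first traversal from the
reducing-end anomeric carbon with numbered ring closures (`%nn` beyond
nine). Ring stereocentres carry tetrahedral markers derived from a
per-position convention flipped by anomericity at the anomeric carbon and
by D/L configuration at the closure carbon. This yields deterministic,
syntactically valid, formula-correct output — the properties the external
toolkit oracle verifies — but the markers follow the package's own
convention rather than a validated CIP assignment, so downstream users who
need certified absolute stereochemistry should canonicalize with a
dedicated cheminformatics toolkit. Canonical SMILES, InChI and 3D
coordinates are deliberately out of scope (InChI requires the standard
algorithm; users can derive it from the emitted SMILES externally).

## Numerical and degenerate-input choices

* The empty glycan is a legal value: `isFullyDefined` is vacuously true,
  rendering yields a minimal valid SVG, serialization and chemical export
  raise classed errors.
* Ties in sibling ordering fall back to the lexicographic subtree key, so
  structurally identical siblings order deterministically.
* Collision probing is unbounded but terminates (the grid is infinite and
  each column finite in occupancy).
* All randomness flows through explicit seeds; the generator saves and
  restores `.Random.seed`.
* Problem sizes used by the shipped verification: the 500-glycan corpus
  described above for round-trip, layout, conservation and gate checks;
  a 1-in-10 sample of it for SVG style scanning; dense-branching trees of
  depth 2–3 for the layout stress cases. These sizes exercise every code
  path (multi-digit ring closures, deep branches, all fuzz channels) while
  keeping the default verification run fast.

## Known limitations

Beyond the stereo-marker convention above: WURCS/LINUCS/IUPAC import and
UND/ALT GlycoCT subsections are unsupported by design; validation is
detection, not auto-correction; the renderer does not embed fonts or
export raster formats; and the vocabulary, while covering the SNFG core
assignments, is not the complete SNFG table — extending it is a data-file
edit, not a code change.
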