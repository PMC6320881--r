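# Fixture builders used across test files. Everything is generated in code;
# no stored fixtures beyond the packaged vocabularies and templates.

lactose <- function() {
  g <- createGlycan(monosaccharide("Glc", "beta"))
  addMonosaccharide(g, 1, monosaccharide("Gal", "beta"), linkage(1, 4))
}

# trimannosyl branch: Man with 3- and 6-linked arms
manBranch <- function() {
  g <- createGlycan(monosaccharide("Man", "beta"))
  g <- addMonosaccharide(g, 1, monosaccharide("Man", "alpha"), linkage(1, 3))
  addMonosaccharide(g, 1, monosaccharide("Man", "alpha"), linkage(1, 6))
}

chain3 <- function() {
  g <- createGlycan(monosaccharide("Glc", "beta"))
  g <- addMonosaccharide(g, 1, monosaccharide("Glc", "beta"), linkage(1, 4))
  addMonosaccharide(g, 2, monosaccharide("Glc", "beta"), linkage(1, 4))
}

# deterministic corpus: n glycans per fuzz level, sizes cycling 1..maxSize
buildCorpus <- function(n, fuzz = 0, maxSize = 40, seedBase = 5000) {
  lapply(seq_len(n), function(i)
    generateRandomGlycan(seedBase + i, 1 + (i * 7) %% maxSize, fuzz))
}

# id-renaming isomorphism via the canonical, id-independent subtree key
glycansIsomorphic <- function(g1, g2) {
  if (glycanSize(g1) != glycanSize(g2)) return(FALSE)
  if (glycanSize(g1) == 0) return(TRUE)
  identical(glycanKit:::.subtreeKey(g1, glycanRoot(g1)),
            glycanKit:::.subtreeKey(g2, glycanRoot(g2)))
}

# glycan saturating every attachable carbon down to a given depth
denseGlycan <- function(depth = 3, type = "Man") {
  g <- createGlycan(monosaccharide(type, "beta"))
  grow <- function(g, id, d) {
    if (d == 0) return(g)
    for (p in glycanKit:::.attachablePositions(type)) {
      g <- addMonosaccharide(g, id, monosaccharide(type, "alpha"),
                             linkage(1, p))
      g <- grow(g, lastNodeId(g), d - 1)
    }
    g
  }
  grow(g, 1, depth)
}

svgEdgeStyles <- function(svg) {
  doc <- xml2::read_xml(svg)
  edges <- xml2::xml_find_all(doc,
    "//*[local-name()='line' and @class='edge']")
  data.frame(
    anomericity = xml2::xml_attr(edges, "data-anomericity"),
    dash = xml2::xml_attr(edges, "stroke-dasharray"),
    stringsAsFactors = FALSE)
}

oracleFormula <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  unname(ChemmineR::MF(sdf, addH = TRUE))
}
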