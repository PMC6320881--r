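# Frozen expected structures below were derived by hand from the GlycoCT
# condensed grammar (RES/LIN/REP line syntax, 'x' fuzziness markers, -1
# unknown positions, '|'-joined alternatives).

test_that("parsing maps residues, linkages and fuzziness onto the model", {
  g <- parseGlycoCT("RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\nLIN\n1:1o(4+1)2d")
  expect_equal(glycanSize(g), 2L)
  root <- getNode(g, glycanRoot(g))
  expect_equal(root@mtype, "Glc")
  expect_equal(root@anomericity, "beta")
  expect_equal(root@ring, "pyranose")
  expect_equal(root@config, "D")
  kid <- getNode(g, childIds(g, glycanRoot(g)))
  expect_equal(kid@mtype, "Gal")
  lnk <- edgeLinkage(g, kid@nodeId)
  expect_equal(lnk@donor, 1L)
  expect_equal(lnk@acceptors, 4L)

  g1 <- parseGlycoCT("RES\n1b:a-dgal-HEX-1:5")
  expect_equal(glycanSize(g1), 1L)
  expect_equal(getNode(g1, 1)@mtype, "Gal")
  expect_equal(getNode(g1, 1)@anomericity, "alpha")

  gx <- parseGlycoCT("RES\n1b:x-dglc-HEX-1:5")
  expect_equal(getNode(gx, 1)@anomericity, "undetermined")
  expect_false(isFullyDefined(gx))

  # unknown position and alternatives
  gf <- parseGlycoCT(paste0("RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\n",
                            "LIN\n1:1o(3|4+1)2d"))
  expect_equal(edgeLinkage(gf, childIds(gf, 1))@acceptors, c(3L, 4L))
  expect_false(isFullyDefined(gf))
})

test_that("writing is canonical and encodes composites per convention", {
  expect_identical(writeGlycoCT(lactose()),
                   "RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\nLIN\n1:1o(4+1)2d\n")
  # GlcN + n-acetyl@2: one b-entry, one s-entry, one LIN line
  g <- createGlycan(monosaccharide("GlcN", "beta"))
  g <- addSubstituent(g, 1, substituent("n-acetyl"), 2)
  txt <- writeGlycoCT(g)
  expect_identical(txt, "RES\n1b:b-dglc-HEX-1:5\n2s:n-acetyl\nLIN\n1:1d(2+1)2n\n")
  # bare amino sugar gets its amino s-entry
  expect_identical(writeGlycoCT(createGlycan(monosaccharide("GlcN", "beta"))),
                   "RES\n1b:b-dglc-HEX-1:5\n2s:amino\nLIN\n1:1d(2+1)2n\n")
  # alternatives join with '|', unknown writes -1
  ga <- addMonosaccharide(lactose(), 2, monosaccharide("Man", "alpha"),
                          linkage(1, c(3, 4)))
  expect_match(writeGlycoCT(ga), "(3|4+1)", fixed = TRUE)
  gu <- addMonosaccharide(lactose(), 2, monosaccharide("Man", "alpha"),
                          linkage(NA, NA))
  expect_match(writeGlycoCT(gu), "(-1+-1)", fixed = TRUE)
  expect_error(writeGlycoCT(emptyGlycan()), class = "glycanEmptyError")
})

test_that("normalization is an idempotent, order/line-ending-insensitive fixpoint", {
  doc <- "RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\nLIN\n1:1o(4+1)2d"
  n1 <- normalizeGlycoCT(doc)
  expect_identical(normalizeGlycoCT(n1), n1)
  crlf <- gsub("\n", "\r\n", doc, fixed = TRUE)
  expect_identical(normalizeGlycoCT(crlf), n1)
  # all sibling orderings of a 4-residue star normalize identically
  combos <- list(c(2, 3, 4), c(2, 4, 3), c(3, 2, 4),
                 c(3, 4, 2), c(4, 2, 3), c(4, 3, 2))
  docs <- vapply(combos, function(ord) {
    g <- createGlycan(monosaccharide("Man", "beta"))
    for (p in ord)
      g <- addMonosaccharide(g, 1, monosaccharide("Glc", "alpha"),
                             linkage(1, p))
    writeGlycoCT(g)
  }, character(1))
  expect_length(unique(vapply(docs, normalizeGlycoCT, character(1))), 1L)
})

test_that("grammar-violating mutations raise parse errors, never misparse", {
  good <- "RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\nLIN\n1:1o(4+1)2d"
  expect_error(parseGlycoCT(sub("1b:", "1b", good, fixed = TRUE)),
               class = "glycoctParseError")                  # deleted colon
  expect_error(parseGlycoCT(sub("1b:", "0b:", good, fixed = TRUE)),
               class = "glycoctParseError")                  # index 0
  expect_error(parseGlycoCT(sub("HEX", "HXX", good, fixed = TRUE)),
               class = "glycoctParseError")                  # unknown superclass
  expect_error(parseGlycoCT(sub("dglc", "qglc", good, fixed = TRUE)),
               class = "glycoctParseError")                  # bad stereo prefix
  expect_error(parseGlycoCT(sub("2d", "9d", good, fixed = TRUE)),
               class = "glycoctReferenceError")              # dangling index
  expect_error(parseGlycoCT(paste0(good, "\nUND")),
               class = "glycoctUnsupportedError")            # UND section
  expect_error(parseGlycoCT("LIN\n1:1o(4+1)2d"),
               class = "glycoctParseError")                  # no RES first
  expect_error(parseGlycoCT("RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5"),
               class = "glycoctReferenceError")              # two roots
  # the error message carries the offending line number
  err <- tryCatch(parseGlycoCT("RES\n1b:b-dglc-HEX-1:5\n2b:junk"),
                  glycoctParseError = function(e) conditionMessage(e))
  expect_match(err, "line 3")
})

test_that("repeat units survive the REP round-trip with their counts", {
  inner <- createGlycan(monosaccharide("Glc", "beta"))
  ru <- repeatUnit(inner, 2, 5, linkage(1, 4))
  g <- createGlycan(monosaccharide("Gal", "beta"))
  g <- addRepeatUnit(g, 1, ru, linkage(1, 3))
  txt <- writeGlycoCT(g)
  expect_match(txt, "REP1:", fixed = TRUE)
  expect_match(txt, "=2-5", fixed = TRUE)
  g2 <- parseGlycoCT(txt)
  ru2 <- Filter(function(n) is(n, "RepeatUnit"),
                lapply(nodeIds(g2), function(i) getNode(g2, i)))[[1]]
  expect_equal(ru2@minCount, 2L)
  expect_equal(ru2@maxCount, 5L)
  expect_identical(writeGlycoCT(g2), txt)
  # unknown bounds write -1 and come back as NA
  ruU <- repeatUnit(inner, NA, NA, linkage(1, 4))
  gU <- addRepeatUnit(createGlycan(monosaccharide("Gal", "beta")), 1,
                      ruU, linkage(1, 3))
  tU <- writeGlycoCT(gU)
  expect_match(tU, "=-1--1", fixed = TRUE)
  ru3 <- Filter(function(n) is(n, "RepeatUnit"),
                lapply(nodeIds(parseGlycoCT(tU)),
                       function(i) getNode(parseGlycoCT(tU), i)))[[1]]
  expect_true(is.na(ru3@minCount) && is.na(ru3@maxCount))
})

test_that("round-trip is isomorphic and byte-stable on a random corpus", {
  corpus <- c(buildCorpus(30, fuzz = 0, seedBase = 7100),
              buildCorpus(30, fuzz = 0.3, seedBase = 7200))
  for (g in corpus) {
    t1 <- writeGlycoCT(g)
    g2 <- parseGlycoCT(t1)
    expect_true(glycansIsomorphic(g, g2))
    expect_identical(writeGlycoCT(g2), t1)
    expect_equal(isFullyDefined(g2), isFullyDefined(g))
  }
})

test_that("reader accepts file paths and writer mirrors to files", {
  tmp <- tempfile(fileext = ".glycoct")
  txt <- writeGlycoCT(lactose(), file = tmp)
  expect_true(file.exists(tmp))
  expect_identical(writeGlycoCT(parseGlycoCT(tmp)), txt)
})
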