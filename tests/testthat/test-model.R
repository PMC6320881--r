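test_that("glycan creation draws from the vocabularies and sets the root", {
  g <- createGlycan(monosaccharide("GlcN", "beta"))
  expect_s4_class(g, "Glycan")
  expect_equal(glycanSize(g), 1L)
  expect_length(g@edges, 0)
  expect_equal(glycanRoot(g), 1L)
  expect_equal(getNode(g, 1)@anomericity, "beta")

  expect_error(monosaccharide("Glcose"), class = "glycanVocabularyError")
  expect_error(substituent("nitrate"), class = "glycanVocabularyError")
  expect_error(monosaccharide("Glc", "alpha", ring = "open"),
               class = "glycanInvariantError")
  # heptose of the worked example renders downstream as a green hexagon
  h <- createGlycan(monosaccharide("LDmanHep", "alpha"))
  s <- symbolFor(getNode(h, 1)@mtype)
  expect_equal(c(s$shape, s$color), c("hexagon", "green"))
})

test_that("monosaccharide attachment enforces occupancy and parent rules", {
  g <- lactose()
  expect_equal(glycanSize(g), 2L)
  expect_length(g@edges, 1)
  expect_equal(lastNodeId(g), 2L)
  # occupied (->4) position
  expect_error(
    addMonosaccharide(g, 1, monosaccharide("Man", "alpha"), linkage(1, 4)),
    class = "glycanConflictError")
  # fuzzy alternatives accepted, flags the glycan as not fully defined
  g2 <- addMonosaccharide(g, 1, monosaccharide("Man", "alpha"),
                          linkage(1, c(3, 6)))
  expect_equal(glycanSize(g2), 3L)
  expect_false(isFullyDefined(g2))
  # substituent cannot be a parent
  s <- addSubstituent(g, 2, substituent("sulfate"), 6)
  expect_error(
    addMonosaccharide(s, lastNodeId(s), monosaccharide("Glc", "beta"),
                      linkage(1, 1)),
    class = "glycanIllegalParentError")
  # out-of-range acceptor
  expect_error(
    addMonosaccharide(g, 1, monosaccharide("Glc", "beta"), linkage(1, 7)),
    class = "glycanRangeError")
})

test_that("substituent attachment covers ranges, conflicts and fuzziness", {
  g <- createGlycan(monosaccharide("Gal", "beta"))
  g <- addSubstituent(g, 1, substituent("sulfate"), 6)
  expect_equal(glycanSize(g), 2L)
  expect_error(addSubstituent(g, 1, substituent("methyl"), 6),
               class = "glycanConflictError")
  expect_error(addSubstituent(g, 1, substituent("sulfate"), 11),
               class = "glycanRangeError")
  gu <- addSubstituent(g, 1, substituent("methyl"), NA)
  expect_equal(glycanSize(gu), 3L)
  expect_false(isFullyDefined(gu))
})

test_that("N-acyl groups at an amine-bearing position canonicalize the base", {
  g <- createGlycan(monosaccharide("Glc", "beta"))
  g <- addSubstituent(g, 1, substituent("n-acetyl"), 2)
  expect_equal(getNode(g, 1)@mtype, "GlcN")
  expect_equal(glycanSize(g), 2L)
  # the pair fuses to the GlcNAc SNFG symbol downstream
  s <- symbolFor("GlcN", data.frame(name = "n-acetyl", position = 2))
  expect_equal(c(s$shape, s$color), c("square", "blue"))
  # amino alone performs the upgrade without adding a node
  h <- createGlycan(monosaccharide("Gal", "beta"))
  h <- addSubstituent(h, 1, substituent("amino"), 2)
  expect_equal(getNode(h, 1)@mtype, "GalN")
  expect_equal(glycanSize(h), 1L)
})

test_that("subtree removal prunes descendants and preserves remaining ids", {
  g <- chain3()
  expect_equal(glycanSize(removeSubtree(g, 3)), 2L)        # leaf
  mid <- removeSubtree(g, 2)                               # middle: prunes 3
  expect_equal(glycanSize(mid), 1L)
  expect_equal(nodeIds(mid), 1L)
  emp <- removeSubtree(g, 1)                               # root
  expect_equal(glycanSize(emp), 0L)
  expect_true(isFullyDefined(emp))                         # vacuously
  # ids are never reused after deletion
  g2 <- addMonosaccharide(mid, 1, monosaccharide("Gal", "beta"),
                          linkage(1, 4))
  expect_equal(lastNodeId(g2), 4L)
  expect_error(removeSubtree(g, 99), class = "glycanMissingNodeError")
})

test_that("node updates replace fields in place and guard consistency", {
  g <- chain3()
  g2 <- updateNode(g, 3, anomericity = "alpha")
  expect_equal(getNode(g2, 3)@anomericity, "alpha")
  expect_equal(length(g2@edges), length(g@edges))
  # shrinking the carbon count below a (->6) child linkage
  g6 <- addMonosaccharide(lactose(), 1, monosaccharide("Man", "alpha"),
                          linkage(1, 6))
  expect_error(updateNode(g6, 1, mtype = "Xyl"),
               class = "glycanConsistencyError")
  # ring change flows through to the GlycoCT ring descriptor
  g3 <- updateNode(g, 3, ring = "furanose")
  expect_match(writeGlycoCT(g3), "b-dglc-HEX-1:4", fixed = TRUE)
})

test_that("copy/paste deep-copies with fresh ids and detects conflicts", {
  # 4-residue antenna on a core with a free (->6)
  core <- createGlycan(monosaccharide("Man", "beta"))
  core <- addMonosaccharide(core, 1, monosaccharide("Man", "alpha"),
                            linkage(1, 3))
  ant <- core
  for (spec in list(c(2, 2), c(3, 4), c(4, 6), c(5, 3))) {
    ant <- addMonosaccharide(ant, spec[1], monosaccharide("Glc", "beta"),
                             linkage(1, spec[2]))
  }
  frag <- copySubtree(ant, 2)
  expect_equal(glycanSize(frag), 5L)
  pasted <- pasteSubtree(ant, 1, frag, linkage(1, 6))
  expect_equal(glycanSize(pasted), glycanSize(ant) + 5L)
  # source untouched by mutating the copy
  frag2 <- updateNode(frag, 1, anomericity = "beta")
  expect_equal(getNode(ant, 2)@anomericity, "alpha")
  expect_equal(getNode(frag2, 1)@anomericity, "beta")
  # occupied position rejects the paste
  expect_error(pasteSubtree(ant, 1, frag, linkage(1, 3)),
               class = "glycanConflictError")
})

test_that("delete then paste of the copied fragment restores the glycan", {
  g <- manBranch()
  g <- addMonosaccharide(g, 2, monosaccharide("Gal", "beta"), linkage(1, 2))
  frag <- copySubtree(g, 2)
  lnk <- edgeLinkage(g, 2)
  cut <- removeSubtree(g, 2)
  restored <- pasteSubtree(cut, 1, frag, lnk)
  expect_true(glycansIsomorphic(g, restored))
})

test_that("fully-defined detection covers every fuzziness channel", {
  expect_true(isFullyDefined(lactose()))
  g <- addMonosaccharide(lactose(), 2, monosaccharide("Man", "alpha"),
                         linkage(1, c(3, 4)))
  expect_false(isFullyDefined(g))
  expect_false(isFullyDefined(createGlycan(monosaccharide("Glc"))))
  expect_false(isFullyDefined(
    createGlycan(monosaccharide("Glc", "beta", config = "undetermined"))))
  g2 <- addMonosaccharide(lactose(), 2, monosaccharide("Man", "alpha"),
                          linkage(1, NA))
  expect_false(isFullyDefined(g2))
  ru <- repeatUnit(createGlycan(monosaccharide("Glc", "beta")),
                   NA, 5, linkage(1, 4))
  g3 <- addRepeatUnit(lactose(), 2, ru, linkage(1, 3))
  expect_false(isFullyDefined(g3))
})

test_that("repeat units behave as single host nodes with positive counts", {
  inner <- createGlycan(monosaccharide("Glc", "beta"))
  ru <- repeatUnit(inner, 2, 5, linkage(1, 4))
  g <- addRepeatUnit(lactose(), 2, ru, linkage(1, 3))
  expect_equal(glycanSize(g), 3L)
  expect_error(repeatUnit(inner, 5, 2, linkage(1, 4)),
               class = "glycanRangeError")
  expect_error(repeatUnit(inner, 0, 5, linkage(1, 4)),
               class = "glycanRangeError")
  expect_error(repeatUnit(emptyGlycan(), 1, 2, linkage(1, 4)),
               class = "glycanRangeError")
})

test_that("random edit scripts preserve the tree property", {
  set.seed(42)
  for (rep in 1:20) {
    g <- generateRandomGlycan(9000 + rep, 12, 0)
    # random deletions and re-additions
    for (step in 1:6) {
      ids <- nodeIds(g)
      op <- sample(c("add", "del"), 1)
      if (op == "del" && glycanSize(g) > 2) {
        victim <- sample(setdiff(ids, glycanRoot(g)), 1)
        g <- removeSubtree(g, victim)
      } else {
        hosts <- Filter(function(i) is(getNode(g, i), "Monosaccharide"), ids)
        host <- if (length(hosts) == 1) hosts[[1]] else sample(hosts, 1)
        free <- setdiff(
          glycanKit:::.attachablePositions(getNode(g, host)@mtype),
          glycanKit:::.statedGlycosidicPositions(g, host))
        if (length(free))
          g <- addMonosaccharide(g, host, monosaccharide("Glc", "beta"),
                                 linkage(1, free[1]))
      }
      expect_equal(length(g@edges), glycanSize(g) - 1L)
      nonRoot <- setdiff(nodeIds(g), glycanRoot(g))
      parents <- vapply(nonRoot, function(i) parentId(g, i), integer(1))
      expect_false(anyNA(parents))
    }
  }
})

test_that("editing one branch leaves sibling subtrees untouched", {
  g <- manBranch()
  g <- addMonosaccharide(g, 2, monosaccharide("Gal", "beta"), linkage(1, 2))
  before <- glycanKit:::.subtreeKey(g, 3)
  g2 <- addMonosaccharide(g, 4, monosaccharide("Fuc", "alpha"), linkage(1, 3))
  g3 <- updateNode(g2, 4, anomericity = "alpha")
  expect_identical(glycanKit:::.subtreeKey(g3, 3), before)
})
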