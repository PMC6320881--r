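test_that("the quick palette has exactly twelve unique, valid entries", {
  p <- quickPalette()
  expect_equal(nrow(p), 12L)
  expect_false(anyDuplicated(p$name) > 0)
  for (nm in p$name) {
    g <- paletteGlycan(nm, "beta")
    expect_true(glycanSize(g) %in% 1:2)
    expect_equal(nrow(validateGlycan(g)), 0L)
  }
})

test_that("quick mode needs two chemistry parameters, normal mode six", {
  # quick: anomericity + acceptor position only
  quickChem <- intersect(names(formals(quickAdd)),
                         c("anomericity", "acceptorPosition"))
  expect_length(quickChem, 2L)
  # normal: type (= SNFG shape+colour), anomericity, ring + donor, acceptor
  normalChem <- c(setdiff(names(formals(monosaccharide)), "config"),
                  names(formals(linkage)))
  expect_length(normalChem, 5L)  # plus absolute configuration = 6
  expect_true(all(c("donor", "acceptors") %in% normalChem))
})

test_that("quick additions infer the donor and block invalid chemistry", {
  g <- createGlycan(monosaccharide("Glc", "beta"))
  g <- quickAdd(g, 1, "Gal", "beta", 4)         # lactose
  expect_true(glycansIsomorphic(g, lactose()))
  expect_equal(edgeLinkage(g, 2)@donor, 1L)     # aldose donates from C1

  h <- createGlycan(monosaccharide("Gal", "beta"))
  h <- quickAdd(h, 1, "Neu5Ac", "alpha", 3)
  sial <- childIds(h, 1)
  expect_equal(edgeLinkage(h, sial[1])@donor, 2L)  # ulosonate from C2

  expect_error(quickAdd(g, 1, "Man", "alpha", 4),
               class = "glycanConflictError")   # occupied
  expect_error(quickAdd(g, 1, "NotInPalette", "alpha", 3),
               class = "glycanVocabularyError")
})

test_that("donor inference follows the aldose/ketose rule for all entries", {
  expect_equal(inferDonorPosition("Glc"), 1L)
  expect_equal(inferDonorPosition("Neu5Ac"), 2L)
  expect_equal(inferDonorPosition("Kdn"), 2L)
  expect_equal(inferDonorPosition(monosaccharide("Fuc", "alpha")), 1L)
  # consistency with the vocabulary's anomeric-carbon column, all types
  mono <- monosaccharideTypes()
  for (i in seq_len(nrow(mono)))
    expect_equal(inferDonorPosition(mono$name[i]), mono$anomeric_carbon[i])
})

test_that("validity rules fire on the documented forbidden combinations", {
  expect_equal(nrow(validateGlycan(lactose())), 0L)
  # R3: aldose donating from C3
  r3 <- parseGlycoCT("RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\nLIN\n1:1o(4+3)2d")
  expect_equal(validateGlycan(r3)$rule, "R3")
  # R5: sulfate and a glycosidic child both at position 6
  g5 <- addSubstituent(lactose(), 1, substituent("sulfate"), 6)
  g5 <- addMonosaccharide(g5, 1, monosaccharide("Man", "alpha"), linkage(1, 6))
  expect_true("R5" %in% validateGlycan(g5)$rule)
  # R5: substituent on the ring-closure carbon
  g5b <- addSubstituent(createGlycan(monosaccharide("Glc", "beta")),
                        1, substituent("acetyl"), 5)
  expect_true("R5" %in% validateGlycan(g5b)$rule)
  # R2 via direct document input (the model constructors block it)
  r2 <- parseGlycoCT("RES\n1b:b-dxyl-PEN-1:5\n2s:sulfate\nLIN\n1:1o(4+1)2n")
  expect_equal(nrow(validateGlycan(r2)), 0L)
})

test_that("the template catalog is intact and includes the worked-example core", {
  t <- listTemplates()
  expect_true(all(c("n-core", "n-core-fucosylated", "o-core-1") %in% t$name))
  expect_true(all(t$category %in% c("N-core", "O-core", "epitope")))
  expect_gte(sum(t$category == "O-core"), 8L)

  nc <- loadTemplate("n-core")
  monos <- Filter(function(i) is(getNode(nc, i), "Monosaccharide"),
                  nodeIds(nc))
  expect_length(monos, 5L)                       # Man3GlcNAc2
  expect_equal(getNode(nc, glycanRoot(nc))@mtype, "GlcN")

  oc1 <- loadTemplate("o-core-1")                # Gal-(1->3)-GalNAc
  expect_equal(getNode(oc1, glycanRoot(oc1))@mtype, "GalN")
  galId <- Filter(function(i) getNode(oc1, i)@mtype == "Gal",
                  Filter(function(i) is(getNode(oc1, i), "Monosaccharide"),
                         nodeIds(oc1)))[[1]]
  expect_equal(edgeLinkage(oc1, galId)@acceptors, 3L)

  expect_error(loadTemplate("z-core"), class = "glycanCatalogError")
  # loading gives an independent deep copy
  a <- loadTemplate("o-core-1"); b <- loadTemplate("o-core-1")
  b <- updateNode(b, glycanRoot(b), anomericity = "beta")
  expect_equal(getNode(a, glycanRoot(a))@anomericity, "alpha")
})

test_that("every template is fully defined, clean, stable and collision-free", {
  for (nm in listTemplates()$name) {
    g <- loadTemplate(nm)
    expect_true(isFullyDefined(g))
    expect_equal(nrow(validateGlycan(g)), 0L)
    txt <- writeGlycoCT(g)
    expect_identical(writeGlycoCT(parseGlycoCT(txt)), txt)
    cells <- layoutCells(layoutGlycan(g))
    expect_false(anyDuplicated(paste(cells$col, cells$row)) > 0)
  }
})

test_that("the random generator is seeded, size-true and contract-faithful", {
  g <- generateRandomGlycan(1, 10, 0)
  expect_equal(glycanSize(g), 10L)
  expect_true(isFullyDefined(g))
  expect_equal(nrow(validateGlycan(g)), 0L)
  expect_identical(writeGlycoCT(generateRandomGlycan(1, 10, 0)),
                   writeGlycoCT(g))
  expect_false(isFullyDefined(generateRandomGlycan(2, 10, 1)))
  expect_false(isFullyDefined(generateRandomGlycan(2, 1, 1)))
  # generator output is validation-sound at fuzz = 0
  for (g in buildCorpus(15, fuzz = 0, seedBase = 7600))
    expect_equal(nrow(validateGlycan(g)), 0L)
  # generation does not disturb the session RNG
  set.seed(99); before <- .Random.seed
  invisible(generateRandomGlycan(3, 5, 0))
  expect_identical(.Random.seed, before)
})
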