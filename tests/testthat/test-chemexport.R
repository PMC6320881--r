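test_that("single residues expand to the correct atomistic templates", {
  glc <- createGlycan(monosaccharide("Glc", "beta"))
  mg <- toMolecularGraph(glc)
  expect_equal(atomCount(mg), 24L)              # C6H12O6 including hydrogens
  expect_equal(graphFormula(mg), "C6H12O6")
  expect_equal(molecularFormula(glc), "C6H12O6")

  glcnac <- paletteGlycan("GlcNAc", "beta")
  expect_equal(molecularFormula(glcnac), "C8H15NO6")
  expect_equal(graphFormula(toMolecularGraph(glcnac)), "C8H15NO6")

  neu5ac <- paletteGlycan("Neu5Ac", "alpha")
  expect_equal(molecularFormula(neu5ac), "C11H19NO9")
  expect_equal(graphFormula(toMolecularGraph(neu5ac)), "C11H19NO9")

  fuc <- createGlycan(monosaccharide("Fuc", "alpha"))
  expect_equal(molecularFormula(fuc), "C6H12O5")

  gal6s <- addSubstituent(createGlycan(monosaccharide("Gal", "beta")),
                          1, substituent("sulfate"), 6)
  expect_equal(molecularFormula(gal6s), "C6H12O9S")
  expect_equal(graphFormula(toMolecularGraph(gal6s)), "C6H12O9S")
})

test_that("glycosidic condensation loses one water per edge", {
  expect_equal(molecularFormula(lactose()), "C12H22O11")  # 2xC6H12O6 - H2O
  expect_equal(graphFormula(toMolecularGraph(lactose())), "C12H22O11")
  tri <- chain3()
  expect_equal(molecularFormula(tri), "C18H32O16")
  # repeat expansion obeys the same law: Gal + 3x Glc - 3 H2O
  ru <- repeatUnit(createGlycan(monosaccharide("Glc", "beta")), 3, 3,
                   linkage(1, 4))
  g <- addRepeatUnit(createGlycan(monosaccharide("Gal", "beta")), 1, ru,
                     linkage(1, 4))
  expect_equal(molecularFormula(g), "C24H42O21")
  expect_equal(graphFormula(toMolecularGraph(g)), "C24H42O21")
})

test_that("the fully-defined gate blocks every fuzzy structure", {
  fuzzy <- createGlycan(monosaccharide("Glc"))        # undetermined anomer
  expect_error(toSMILES(fuzzy), class = "glycanUnderdeterminedError")
  expect_error(toMolecularGraph(fuzzy), class = "glycanUnderdeterminedError")
  expect_error(molecularFormula(fuzzy), class = "glycanUnderdeterminedError")
  alt <- addMonosaccharide(lactose(), 2, monosaccharide("Man", "alpha"),
                           linkage(1, c(3, 4)))
  expect_error(toSMILES(alt), class = "glycanUnderdeterminedError")
  expect_error(toSMILES(emptyGlycan()), class = "glycanEmptyError")
  # ambiguous repeat count is chemically underdetermined
  ru <- repeatUnit(createGlycan(monosaccharide("Glc", "beta")), 2, 5,
                   linkage(1, 4))
  amb <- addRepeatUnit(createGlycan(monosaccharide("Gal", "beta")), 1, ru,
                       linkage(1, 3))
  expect_error(toSMILES(amb), class = "glycanUnderdeterminedError")
})

test_that("emitted SMILES are deterministic and parse in an external toolkit", {
  smi <- toSMILES(lactose())
  expect_identical(toSMILES(lactose()), smi)
  expect_equal(oracleFormula(smi), "C12H22O11")
  expect_equal(oracleFormula(toSMILES(createGlycan(
    monosaccharide("Glc", "beta")))), "C6H12O6")
  # a handful of corpus members through the toolkit oracle
  for (g in buildCorpus(6, fuzz = 0, maxSize = 15, seedBase = 7700)) {
    smi <- toSMILES(g)
    expect_equal(oracleFormula(smi), molecularFormula(g))
  }
})

test_that("formula conservation holds between both routes on a corpus", {
  for (g in buildCorpus(25, fuzz = 0, seedBase = 7800)) {
    mg <- toMolecularGraph(g)
    expect_equal(graphFormula(mg), molecularFormula(g))
    # provenance maps every atom to a residue of the expanded glycan
    expect_false(anyNA(mg@atoms$nodeId))
    # graph of a connected glycan is connected
    n <- nrow(mg@atoms)
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nb <- c(mg@bonds$atom2[mg@bonds$atom1 == a],
              mg@bonds$atom1[mg@bonds$atom2 == a])
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    expect_true(all(seen))
  }
})
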