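## Construction interfaces. Quick mode exposes the twelve monosaccharides
## most common in mammalian glycans and asks only two chemistry parameters
## per residue (anomericity of the linkage and the acceptor position); the
## donor position is inferred from the residue class (aldoses donate from
## C1, ketoses/ulosonates from C2) and absolute configuration and ring form
## come from the palette defaults. Normal mode is the full monosaccharide()/
## linkage() surface (shape+colour i.e. type, anomericity, ring, donor and
## acceptor). Chemical-validity rules are advisory in normal mode and
## blocking in quick mode.

.paletteTable <- function() {
  data.frame(
    name = c("Glc", "Gal", "Man", "GlcNAc", "GalNAc", "GlcA",
             "IdoA", "Fuc", "Xyl", "Neu5Ac", "Neu5Gc", "Kdn"),
    base = c("Glc", "Gal", "Man", "GlcN", "GalN", "GlcA",
             "IdoA", "Fuc", "Xyl", "Neu", "Neu", "Kdn"),
    substituent = c(NA, NA, NA, "n-acetyl", "n-acetyl", NA,
                    NA, NA, NA, "n-acetyl", "n-glycolyl", NA),
    position = c(NA, NA, NA, 2L, 2L, NA, NA, NA, NA, 5L, 5L, NA),
    stringsAsFactors = FALSE)
}

#' The quick-mode palette
#'
#' Exactly twelve entries, in fixed order, covering the monosaccharides most
#' commonly found in mammalian glycans. Each entry expands to a base
#' vocabulary type plus any implied substituent (GlcNAc = GlcN + N-acetyl at
#' C2), with the type's default absolute configuration and ring form.
#'
#' @return A data.frame with columns \code{name}, \code{base},
#'   \code{substituent}, \code{position}, \code{config}, \code{ring},
#'   \code{donor}.
#' @export
#' @examples
#' nrow(quickPalette())  # 12
quickPalette <- function() {
  p <- .paletteTable()
  mono <- monosaccharideTypes()
  i <- match(p$base, mono$name)
  p$config <- mono$default_config[i]
  p$ring <- ifelse(mono$default_ring[i] == "f", "furanose", "pyranose")
  p$donor <- mono$anomeric_carbon[i]
  p
}

.paletteEntry <- function(name) {
  p <- quickPalette()
  i <- match(name, p$name)
  if (is.na(i))
    glyStop("glycanVocabularyError",
            sprintf("'%s' is not a quick-palette entry", name))
  as.list(p[i, ])
}

#' Expand a palette entry into a one-residue glycan
#'
#' @param name Palette display name (e.g. "GlcNAc").
#' @param anomericity Anomericity of the reducing-end residue.
#' @return A \linkS4class{Glycan} with the base residue and any implied
#'   substituent.
#' @export
paletteGlycan <- function(name, anomericity = "undetermined") {
  e <- .paletteEntry(name)
  g <- createGlycan(monosaccharide(e$base, anomericity))
  if (!is.na(e$substituent))
    g <- addSubstituent(g, lastNodeId(g), substituent(e$substituent),
                        e$position)
  g
}

#' Infer the donor position of a residue
#'
#' Aldoses donate from C1; ketoses and ulosonates (Neu5Ac, Kdn, Kdo, Fru)
#' from C2. Accepts a palette display name, a vocabulary type token or a
#' \linkS4class{Monosaccharide}.
#'
#' @param x Residue (name or object).
#' @return Integer donor position (the anomeric carbon).
#' @export
#' @examples
#' inferDonorPosition("Glc")     # 1
#' inferDonorPosition("Neu5Ac")  # 2
inferDonorPosition <- function(x) {
  if (is(x, "Monosaccharide")) return(.anomericCarbon(x@mtype))
  p <- .paletteTable()
  i <- match(x, p$name)
  type <- if (!is.na(i)) p$base[i] else x
  ac <- .anomericCarbon(type)
  if (is.na(ac))
    glyStop("glycanVocabularyError", sprintf("unknown residue '%s'", x))
  ac
}

#' Quick-mode residue addition
#'
#' Attaches a palette residue given only the two quick-mode chemistry
#' parameters: the anomericity of the new linkage and the acceptor position
#' on the parent. The donor position, absolute configuration, ring form and
#' implied substituents are filled in from the palette. Quick mode is
#' blocking: the result must pass all chemical-validity rules.
#'
#' @param g A \linkS4class{Glycan}.
#' @param parentId Parent residue id.
#' @param entry Palette display name.
#' @param anomericity "alpha" or "beta".
#' @param acceptorPosition Attachment position on the parent.
#' @return The extended glycan; the base residue's id via the usual
#'   contract is \code{lastNodeId(g)} minus the number of implied
#'   substituents.
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("Glc", "beta"))
#' g <- quickAdd(g, 1, "Gal", "beta", 4)   # lactose
quickAdd <- function(g, parentId, entry, anomericity, acceptorPosition) {
  e <- .paletteEntry(entry)
  res <- monosaccharide(e$base, anomericity)
  g2 <- addMonosaccharide(g, parentId, res,
                          linkage(e$donor, acceptorPosition))
  baseId <- lastNodeId(g2)
  if (!is.na(e$substituent))
    g2 <- addSubstituent(g2, baseId, substituent(e$substituent), e$position)
  v <- validateGlycan(g2)
  if (nrow(v))
    glyStop("glycanValidationError",
            paste("quick-mode addition rejected:",
                  paste(v$rule, v$message, sep = ": ", collapse = "; ")))
  g2
}

## ring-closure carbon of a residue, NA when the ring is open/undetermined
.ringClosure <- function(nd) {
  ac <- .anomericCarbon(nd@mtype)
  switch(nd@ring, pyranose = ac + 4L, furanose = ac + 3L, NA_integer_)
}

#' Chemical-validity rules
#'
#' Scans a glycan for chemically forbidden combinations and returns them as
#' data, not exceptions. Rules: \describe{
#'   \item{R1}{duplicate occupancy of a fully-stated acceptor position;}
#'   \item{R2}{a stated position exceeds the residue's carbon count;}
#'   \item{R3}{a stated donor position differs from the donor residue's
#'     anomeric carbon;}
#'   \item{R4}{an open-chain residue with alpha/beta anomericity;}
#'   \item{R5}{a substituent on the ring-closure carbon or on a
#'     glycosidically occupied carbon.}}
#'
#' @param g A \linkS4class{Glycan}.
#' @return data.frame with columns \code{rule}, \code{nodeId},
#'   \code{message}; zero rows when clean.
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("Glc", "beta"))
#' validateGlycan(g)   # clean
validateGlycan <- function(g) {
  rule <- character(0); nodeId <- integer(0); message <- character(0)
  hit <- function(r, id, msg) {
    rule <<- c(rule, r); nodeId <<- c(nodeId, as.integer(id))
    message <<- c(message, msg)
  }
  for (nd in g@nodes) {
    if (is(nd, "Monosaccharide") && nd@ring == "open" &&
        nd@anomericity %in% c("alpha", "beta"))
      hit("R4", nd@nodeId, "open-chain residue with alpha/beta anomericity")
    if (is(nd, "RepeatUnit")) {
      inner <- validateGlycan(nd@internal)
      if (nrow(inner)) for (i in seq_len(nrow(inner)))
        hit(inner$rule[i], nd@nodeId,
            paste("inside repeat:", inner$message[i]))
    }
  }
  for (e in g@edges) {
    p <- g@nodes[[as.character(e$parent)]]
    k <- g@nodes[[as.character(e$child)]]
    a <- e$linkage@acceptors
    if (is(p, "Monosaccharide")) {
      cc <- .carbonCount(p@mtype)
      if (any(!is.na(a) & a > cc))
        hit("R2", e$parent,
            sprintf("position %s exceeds carbon count %d",
                    paste(a[!is.na(a) & a > cc], collapse = ","), cc))
    }
    if (is(k, "Monosaccharide")) {
      cc <- .carbonCount(k@mtype)
      d <- e$linkage@donor
      if (!is.na(d) && d > cc)
        hit("R2", e$child, sprintf("donor position %d exceeds carbon count %d", d, cc))
      else if (!is.na(d) && d != .anomericCarbon(k@mtype))
        hit("R3", e$child,
            sprintf("donor position %d differs from anomeric carbon %d of %s",
                    d, .anomericCarbon(k@mtype), k@mtype))
    }
  }
  ## per-parent occupancy: R1 duplicates, R5 substituent clashes
  parents <- unique(vapply(g@edges, function(e) e$parent, integer(1)))
  for (pid in parents) {
    p <- g@nodes[[as.character(pid)]]
    es <- .childEdges(g, pid)
    stated <- lapply(es, function(e) {
      a <- e$linkage@acceptors
      if (length(a) == 1L && !is.na(a)) a else NA_integer_
    })
    isSub <- vapply(es, function(e)
      is(g@nodes[[as.character(e$child)]], "Substituent"), logical(1))
    posVec <- unlist(stated)
    for (pos in unique(posVec[!is.na(posVec)])) {
      at <- which(!is.na(posVec) & posVec == pos)
      nGly <- sum(!isSub[at]); nSub <- sum(isSub[at])
      if (nGly > 1L || nSub > 1L)
        hit("R1", pid, sprintf("position %d occupied more than once", pos))
      else if (nGly >= 1L && nSub >= 1L)
        hit("R5", pid,
            sprintf("substituent and glycosidic bond share position %d", pos))
    }
    if (is(p, "Monosaccharide")) {
      rc <- .ringClosure(p)
      if (!is.na(rc) && any(isSub & !is.na(posVec) & posVec == rc))
        hit("R5", pid,
            sprintf("substituent on ring-closure carbon %d", rc))
    }
  }
  data.frame(rule = rule, nodeId = nodeId, message = message,
             stringsAsFactors = FALSE)
}

## ------------------------------------------------------------ templates --

.templateIndex <- function() {
  path <- system.file("extdata", "templates", "index.tsv", package = "glycanKit")
  if (path == "") path <- file.path("inst", "extdata", "templates", "index.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Template catalog of N-/O-glycan cores and epitopes
#'
#' \code{listTemplates} returns the catalog (name + category);
#' \code{loadTemplate} parses the stored GlycoCT file into a fresh
#' \linkS4class{Glycan} (a deep copy, safe to mutate).
#'
#' @param name Template name from \code{listTemplates()$name}.
#' @return \code{listTemplates}: data.frame; \code{loadTemplate}: a Glycan.
#' @export
#' @examples
#' head(listTemplates())
#' glycanSize(loadTemplate("n-core"))  # Man3GlcNAc2
listTemplates <- function() .templateIndex()[, c("name", "category")]

#' @rdname listTemplates
#' @export
loadTemplate <- function(name) {
  idx <- .templateIndex()
  i <- match(name, idx$name)
  if (is.na(i))
    glyStop("glycanCatalogError", sprintf("unknown template '%s'", name))
  path <- system.file("extdata", "templates", idx$file[i],
                      package = "glycanKit")
  if (path == "") path <- file.path("inst", "extdata", "templates", idx$file[i])
  parseGlycoCT(path)
}

## ----------------------------------------------------- random generator --

## positions of a residue type available for glycosidic/substituent
## attachment: all carbons except the anomeric centre, the ring-closure
## carbon (default ring), modified carbons and the amine position
.attachablePositions <- function(type) {
  mt <- .getMonoType(type)
  cc <- mt$carbon_count
  ac <- mt$anomeric_carbon
  blocked <- c(ac, if (mt$default_ring == "f") ac + 3L else ac + 4L)
  for (m in .monoMods(type))
    blocked <- c(blocked, as.integer(sub(":.*$", "", m)))
  if (!is.na(mt$amine_position)) blocked <- c(blocked, mt$amine_position)
  setdiff(seq_len(cc), blocked)
}

#' Seeded random glycan generator
#'
#' Builds a random validity-rule-conformant glycan tree for use as a test
#' corpus. Deterministic per seed (the session RNG state is saved and
#' restored). \code{fuzzProb} injects UNKNOWN positions, alternative
#' acceptor sets and undetermined anomericity/ring/configuration; with
#' \code{fuzzProb = 0} the result is fully defined and \code{validateGlycan}
#' returns no violations.
#'
#' @param seed Integer seed.
#' @param nNodes Target node count (monosaccharide + substituent nodes).
#' @param fuzzProb Probability in [0, 1] of fuzzing each added residue.
#' @return A \linkS4class{Glycan}.
#' @export
#' @examples
#' g <- generateRandomGlycan(1, 10)
#' glycanSize(g)
generateRandomGlycan <- function(seed, nNodes, fuzzProb = 0) {
  stopifnot(nNodes >= 1, fuzzProb >= 0, fuzzProb <= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  pool <- c("Glc", "Gal", "Man", "GlcNAc", "GalNAc", "Fuc", "Xyl",
            "Neu5Ac", "Kdn", "GlcA", "LDmanHep", "Rha")
  poolBase <- c(Glc = "Glc", Gal = "Gal", Man = "Man", GlcNAc = "GlcN",
                GalNAc = "GalN", Fuc = "Fuc", Xyl = "Xyl", Neu5Ac = "Neu",
                Kdn = "Kdn", GlcA = "GlcA", LDmanHep = "LDmanHep", Rha = "Rha")
  poolSub <- c(GlcNAc = "n-acetyl", GalNAc = "n-acetyl", Neu5Ac = "n-acetyl")
  poolSubPos <- c(GlcNAc = 2L, GalNAc = 2L, Neu5Ac = 5L)
  decorations <- c("methyl", "acetyl", "sulfate", "phosphate")

  free <- list()  # nodeId -> free acceptor positions
  pickType <- function(maxNew) {
    cand <- pool
    if (maxNew < 2L) cand <- cand[!cand %in% names(poolSub)]
    sample(cand, 1)
  }
  fuzzResidue <- function(nd) {
    what <- sample(c("anomericity", "ring", "config"), 1)
    if (what == "anomericity") nd@anomericity <- "undetermined"
    else if (what == "ring") nd@ring <- "undetermined"
    else nd@config <- "undetermined"
    nd
  }

  rootEntry <- pickType(nNodes)
  rootType <- poolBase[[rootEntry]]
  root <- monosaccharide(rootType, sample(c("alpha", "beta"), 1))
  if (stats::runif(1) < fuzzProb) root <- fuzzResidue(root)
  g <- createGlycan(root)
  free[["1"]] <- .attachablePositions(rootType)
  n <- 1L
  if (rootEntry %in% names(poolSub) && n < nNodes) {
    g <- addSubstituent(g, 1L, substituent(poolSub[[rootEntry]]),
                        poolSubPos[[rootEntry]])
    n <- n + 1L
  }

  while (n < nNodes) {
    hosts <- names(free)[vapply(free, length, integer(1)) > 0L]
    if (!length(hosts)) break  # saturated (rare; guarded by type choice)
    host <- if (length(hosts) == 1L) hosts else sample(hosts, 1)
    hostId <- as.integer(host)
    slots <- free[[host]]
    pos <- if (length(slots) == 1L) slots else sample(slots, 1)
    totalFree <- sum(vapply(free, length, integer(1)))

    if (n < nNodes && stats::runif(1) < 0.15) {
      g <- addSubstituent(g, hostId, substituent(sample(decorations, 1)), pos)
      free[[host]] <- setdiff(slots, pos)
      n <- n + 1L
      next
    }

    entry <- pickType(nNodes - n)
    type <- poolBase[[entry]]
    nd <- monosaccharide(type, sample(c("alpha", "beta"), 1))
    acc <- pos
    if (stats::runif(1) < fuzzProb) {
      action <- sample(c("residue", "unknown-acceptor", "alternatives"), 1)
      if (action == "residue") nd <- fuzzResidue(nd)
      else if (action == "unknown-acceptor") acc <- NA_integer_
      else if (length(slots) >= 2L) acc <- sort(sample(slots, 2)) else acc <- NA_integer_
    }
    g <- addMonosaccharide(g, hostId, nd, linkage(.anomericCarbon(type), acc))
    newId <- lastNodeId(g)
    consumed <- if (all(is.na(acc))) integer(0) else acc
    free[[host]] <- setdiff(slots, consumed)
    free[[as.character(newId)]] <- .attachablePositions(type)
    n <- n + 1L
    if (entry %in% names(poolSub) && n < nNodes) {
      g <- addSubstituent(g, newId, substituent(poolSub[[entry]]),
                          poolSubPos[[entry]])
      n <- n + 1L
    }
  }
  g
}
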