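## GlycoCT condensed import/export. The writer is deterministic: residues are
## emitted depth-first from the reducing end with siblings in canonical order
## (substituents first, then glycosidic children by smallest stated acceptor
## position, UNKNOWN last, ties broken on the id-independent subtree key).
## UNKNOWN positions are written as -1, alternative acceptor sets as "3|4".
## The parser accepts LF or CRLF, reports line numbers on malformed input and
## rejects UND sections explicitly (fuzziness is expressed inline instead).

.anomerToToken <- c(alpha = "a", beta = "b", open = "o", undetermined = "x")
.tokenToAnomer <- c(a = "alpha", b = "beta", o = "open", x = "undetermined")

.monoDescriptor <- function(nd) {
  mt <- .getMonoType(nd@mtype)
  segs <- strsplit(mt$stereo, "-", fixed = TRUE)[[1]]
  last <- segs[length(segs)]
  letter <- switch(nd@config, D = "d", L = "l", undetermined = "x")
  segs[length(segs)] <- paste0(letter, substring(last, 2))
  ac <- mt$anomeric_carbon
  ring <- switch(nd@ring,
                 pyranose = sprintf("%d:%d", ac, ac + 4L),
                 furanose = sprintf("%d:%d", ac, ac + 3L),
                 open = "0:0",
                 undetermined = "x:x")
  desc <- paste(.anomerToToken[[nd@anomericity]],
                paste(segs, collapse = "-"), mt$superclass, ring, sep = "-")
  mods <- sort(.monoMods(nd@mtype))
  if (length(mods)) desc <- paste(c(desc, mods), collapse = "|")
  desc
}

.accString <- function(acceptors) {
  if (all(is.na(acceptors))) return("-1")
  paste(sort(acceptors), collapse = "|")
}

## last monosaccharide leaf in canonical depth-first order (default repeat
## attachment point)
.canonicalLastLeaf <- function(g) {
  leaf <- NA_integer_
  walk <- function(id) {
    nd <- g@nodes[[as.character(id)]]
    glyc <- Filter(function(e) !is(g@nodes[[as.character(e$child)]], "Substituent"),
                   .orderChildEdges(g, id))
    if (is(nd, "Monosaccharide") && length(glyc) == 0L) leaf <<- id
    for (e in glyc) walk(e$child)
  }
  walk(g@rootId)
  leaf
}

#' Write a glycan as GlycoCT condensed text
#'
#' Produces a deterministic, canonical document: \code{write(parse(write(g)))}
#' is byte-identical to \code{write(g)}. Substituent nodes become
#' \code{s}-entries; amino sugars (GlcN, GalN, ManN, Neu) are emitted as
#' their parent basetype plus an \code{amino} s-entry, or as the standard
#' single N-acyl s-entry when they carry an N-acetyl/N-glycolyl group, as
#' GlycoCT convention requires. Repeat units are emitted as REP blocks.
#'
#' @param g A non-empty \linkS4class{Glycan}.
#' @param file Optional path; when given, the text is also written there.
#' @return The GlycoCT document as a single string (LF line endings).
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("Glc", "beta"))
#' g <- addMonosaccharide(g, 1, monosaccharide("Gal", "beta"), linkage(1, 4))
#' cat(writeGlycoCT(g))
writeGlycoCT <- function(g, file = NULL) {
  if (glycanSize(g) == 0L)
    glyStop("glycanEmptyError", "cannot serialize an empty glycan")
  st <- new.env(parent = emptyenv())
  st$res <- 0L; st$lin <- 0L; st$rep <- 0L
  st$repQueue <- list()

  emitResidue <- function(gg, id, sink) {
    nd <- gg@nodes[[as.character(id)]]
    if (is(nd, "RepeatUnit")) {
      st$rep <- st$rep + 1L; k <- st$rep
      st$res <- st$res + 1L; idx <- st$res
      sink$resLines <- c(sink$resLines, sprintf("%dr:r%d", idx, k))
      st$repQueue[[length(st$repQueue) + 1L]] <- list(k = k, unit = nd)
      sink$idMap[[as.character(id)]] <- idx
      for (e in .orderChildEdges(gg, id)) {
        cidx <- emitResidue(gg, e$child, sink)
        st$lin <- st$lin + 1L
        sink$linLines <- c(sink$linLines,
          sprintf("%d:%do(%s+%s)%dd", st$lin, idx,
                  .accString(e$linkage@acceptors), .fmtPos(e$linkage@donor), cidx))
      }
      return(idx)
    }
    st$res <- st$res + 1L; idx <- st$res
    sink$resLines <- c(sink$resLines,
                       sprintf("%db:%s", idx, .monoDescriptor(nd)))
    sink$idMap[[as.character(id)]] <- idx
    amine <- .aminePosition(nd@mtype)
    amineCovered <- FALSE
    es <- .orderChildEdges(gg, id)
    for (e in es) {
      kid <- gg@nodes[[as.character(e$child)]]
      if (!is(kid, "Substituent")) next
      pos <- e$linkage@acceptors
      isAcyl <- kid@stype %in% c("n-acetyl", "n-glycolyl")
      if (!is.na(amine) && length(pos) == 1L && !is.na(pos) &&
          pos == amine && isAcyl) {
        ptype <- "d"; amineCovered <- TRUE
      } else {
        ptype <- .getSubType(kid@stype)$mode
      }
      st$res <- st$res + 1L; sidx <- st$res
      sink$resLines <- c(sink$resLines, sprintf("%ds:%s", sidx, kid@stype))
      st$lin <- st$lin + 1L
      sink$linLines <- c(sink$linLines,
        sprintf("%d:%d%s(%s+1)%dn", st$lin, idx, ptype, .accString(pos), sidx))
    }
    if (!is.na(amine) && !amineCovered) {
      st$res <- st$res + 1L; sidx <- st$res
      sink$resLines <- c(sink$resLines, sprintf("%ds:amino", sidx))
      st$lin <- st$lin + 1L
      sink$linLines <- c(sink$linLines,
        sprintf("%d:%dd(%d+1)%dn", st$lin, idx, amine, sidx))
    }
    for (e in es) {
      kid <- gg@nodes[[as.character(e$child)]]
      if (is(kid, "Substituent")) next
      cidx <- emitResidue(gg, e$child, sink)
      st$lin <- st$lin + 1L
      sink$linLines <- c(sink$linLines,
        sprintf("%d:%do(%s+%s)%dd", st$lin, idx,
                .accString(e$linkage@acceptors), .fmtPos(e$linkage@donor), cidx))
    }
    idx
  }

  newSink <- function() {
    s <- new.env(parent = emptyenv())
    s$resLines <- character(0); s$linLines <- character(0)
    s$idMap <- list()
    s
  }

  top <- newSink()
  emitResidue(g, g@rootId, top)
  out <- c("RES", top$resLines)
  if (length(top$linLines)) out <- c(out, "LIN", top$linLines)

  repTexts <- character(0)
  qi <- 1L
  while (qi <= length(st$repQueue)) {
    item <- st$repQueue[[qi]]; qi <- qi + 1L
    unit <- item$unit
    sink <- newSink()
    gi <- unit@internal
    rootIdx <- emitResidue(gi, gi@rootId, sink)
    leafNode <- if (!is.na(unit@acceptorNodeId)) unit@acceptorNodeId
                else .canonicalLastLeaf(gi)
    leafIdx <- sink$idMap[[as.character(leafNode)]]
    il <- unit@internalLinkage
    head <- sprintf("REP%d:%do(%s+%s)%dd=%s-%s", item$k, leafIdx,
                    .accString(il@acceptors), .fmtPos(il@donor), rootIdx,
                    .fmtPos(unit@minCount), .fmtPos(unit@maxCount))
    block <- c(head, "RES", sink$resLines)
    if (length(sink$linLines)) block <- c(block, "LIN", sink$linLines)
    repTexts <- c(repTexts, block)
  }
  if (length(repTexts)) out <- c(out, "REP", repTexts)

  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(text, file, sep = "")
  text
}

## ---------------------------------------------------------------- parser --

.getSubTypeChecked <- function(entry) {
  tryCatch(.getSubType(entry$desc),
           glycanVocabularyError = function(e)
             .parseError(entry$line,
                         sprintf("unknown substituent '%s'", entry$desc)))
  invisible(NULL)
}

.parseError <- function(lineNo, msg)
  glyStop("glycoctParseError", sprintf("GlycoCT parse error at line %d: %s",
                                       lineNo, msg))

.parsePosSet <- function(s) {
  if (s == "-1") return(NA_integer_)
  sort(as.integer(strsplit(s, "|", fixed = TRUE)[[1]]))
}

#' Parse GlycoCT condensed text into a Glycan
#'
#' Accepts a document string or a path to a \code{.glycoct} file. Fuzzy
#' markers (\code{x} descriptors, \code{-1} positions, \code{"3|4"}
#' alternative sets) map to the model's UNKNOWN/alternative encodings.
#' Malformed lines raise a parse error naming the line; UND sections raise
#' an explicit unsupported-feature error; indices that do not resolve raise
#' a reference error.
#'
#' @param x GlycoCT condensed text (or a file path).
#' @return A \linkS4class{Glycan}.
#' @export
#' @examples
#' parseGlycoCT("RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\nLIN\n1:1o(4+1)2d")
parseGlycoCT <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  x <- gsub("\r\n", "\n", x, fixed = TRUE)
  x <- gsub("\r", "\n", x, fixed = TRUE)
  lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
  nums <- seq_along(lines)
  keep <- trimws(lines) != ""
  lines <- trimws(lines[keep]); nums <- nums[keep]
  if (!length(lines)) glyStop("glycoctParseError", "empty document")
  if (lines[1] != "RES") .parseError(nums[1], "document must start with RES")

  ## split into blocks: block 0 = top level, then one per REP<k> header
  blocks <- list()
  cur <- list(rep = NULL, res = list(), lin = list(), headerLine = NA_integer_)
  section <- "RES"
  expectedRes <- 1L; expectedLin <- 1L
  flush <- function() { blocks[[length(blocks) + 1L]] <<- cur }
  i <- 2L
  inRepArea <- FALSE
  while (i <= length(lines)) {
    ln <- lines[i]; no <- nums[i]
    if (ln == "UND")
      glyStop("glycoctUnsupportedError",
              "UND sections are not supported; express fuzziness inline")
    if (ln == "RES") { section <- "RES"; i <- i + 1L; next }
    if (ln == "LIN") { section <- "LIN"; i <- i + 1L; next }
    if (ln == "REP") { inRepArea <- TRUE; section <- "REPHEAD"; i <- i + 1L; next }
    m <- regmatches(ln, regexec("^REP([0-9]+):([0-9]+)o\\((-1|[0-9]+(\\|[0-9]+)*)\\+(-1|[0-9]+)\\)([0-9]+)d=(-1|[0-9]+)-(-1|[0-9]+)$", ln))[[1]]
    if (length(m)) {
      if (!inRepArea) .parseError(no, "REP entry outside REP section")
      flush()
      cur <- list(rep = as.integer(m[2]),
                  leafIdx = as.integer(m[3]),
                  accPos = .parsePosSet(m[4]),
                  donPos = if (m[6] == "-1") NA_integer_ else as.integer(m[6]),
                  rootIdx = as.integer(m[7]),
                  minCount = if (m[8] == "-1") NA_integer_ else as.integer(m[8]),
                  maxCount = if (m[9] == "-1") NA_integer_ else as.integer(m[9]),
                  res = list(), lin = list(), headerLine = no)
      section <- "RES"
      i <- i + 1L; next
    }
    if (section == "REPHEAD") .parseError(no, "expected a REP<k>: entry")
    if (section == "RES") {
      m <- regmatches(ln, regexec("^([0-9]+)([bsr]):(.+)$", ln))[[1]]
      if (!length(m)) .parseError(no, "malformed RES entry")
      idx <- as.integer(m[2])
      if (idx != expectedRes)
        .parseError(no, sprintf("RES index %d out of order (expected %d)",
                                idx, expectedRes))
      expectedRes <- expectedRes + 1L
      cur$res[[length(cur$res) + 1L]] <-
        list(idx = idx, kind = m[3], desc = m[4], line = no)
    } else if (section == "LIN") {
      m <- regmatches(ln, regexec(
        "^([0-9]+):([0-9]+)([odhn])\\((-1|[0-9]+(\\|[0-9]+)*)\\+(-1|[0-9]+)\\)([0-9]+)([odhn])$",
        ln))[[1]]
      if (!length(m)) .parseError(no, "malformed LIN entry")
      if (as.integer(m[2]) != expectedLin)
        .parseError(no, sprintf("LIN index %s out of order", m[2]))
      expectedLin <- expectedLin + 1L
      cur$lin[[length(cur$lin) + 1L]] <-
        list(parent = as.integer(m[3]), ptype = m[4],
             acc = .parsePosSet(m[5]),
             don = if (m[7] == "-1") NA_integer_ else as.integer(m[7]),
             child = as.integer(m[8]), ctype = m[9], line = no)
    } else .parseError(no, "unexpected content")
    i <- i + 1L
  }
  flush()

  resTable <- list()   # global idx -> parsed entry
  for (b in blocks) for (r in b$res) resTable[[as.character(r$idx)]] <- r
  repBlocks <- list()
  for (b in blocks) if (!is.null(b$rep)) repBlocks[[as.character(b$rep)]] <- b

  built <- new.env(parent = emptyenv())  # memo of built rep blocks

  parseMono <- function(entry) {
    m <- regmatches(entry$desc, regexec(
      "^([abox])-((?:[dlx][a-z]{3}-)*[dlx][a-z]{3})-(TRI|TET|PEN|HEX|HEP|OCT|NON)-([0-9]+:[0-9]+|x:x|0:0)((\\|[0-9]+:[a-z]+)*)$",
      entry$desc))[[1]]
    if (!length(m)) .parseError(entry$line, "malformed basetype descriptor")
    anomer <- .tokenToAnomer[[m[2]]]
    segs <- strsplit(m[3], "-", fixed = TRUE)[[1]]
    last <- segs[length(segs)]
    letter <- substring(last, 1, 1)
    config <- switch(letter, d = "D", l = "L", x = "undetermined")
    segs[length(segs)] <- substring(last, 2)
    mods <- .parseMods(gsub("|", ",", sub("^\\|", "", m[6]), fixed = TRUE))
    key <- paste(paste(segs, collapse = "-"), m[4],
                 paste(sort(mods), collapse = ","), sep = "/")
    type <- unname(.vocabGet("descLookup")[key])
    if (is.na(type))
      .parseError(entry$line,
                  sprintf("unknown monosaccharide descriptor '%s'", entry$desc))
    ac <- .anomericCarbon(type)
    ring <- m[5]
    if (ring == "x:x") ringForm <- "undetermined"
    else if (ring == "0:0") {
      ringForm <- "open"
      if (anomer != "open")
        .parseError(entry$line, "open-chain ring requires anomer 'o'")
    } else {
      se <- as.integer(strsplit(ring, ":", fixed = TRUE)[[1]])
      if (se[1] != ac)
        .parseError(entry$line, "ring start does not match anomeric carbon")
      span <- se[2] - se[1]
      ringForm <- if (span == 4L) "pyranose" else if (span == 3L) "furanose"
                  else .parseError(entry$line, "unsupported ring size")
      if (anomer == "open")
        .parseError(entry$line, "anomer 'o' requires open-chain ring 0:0")
    }
    list(type = type, anomericity = anomer, ring = ringForm, config = config)
  }

  buildBlock <- function(b) {
    resIdx <- vapply(b$res, `[[`, integer(1), "idx")
    kinds <- vapply(b$res, `[[`, character(1), "kind")
    byIdx <- structure(b$res, names = as.character(resIdx))
    ## validate descriptors up front so malformed entries surface as parse
    ## errors with their line number, not downstream structure errors
    for (r in b$res) if (r$kind == "b") parseMono(r)
      else if (r$kind == "s") .getSubTypeChecked(r)
    for (l in b$lin) {
      if (!as.character(l$parent) %in% names(byIdx) ||
          !as.character(l$child) %in% names(byIdx))
        glyStop("glycoctReferenceError",
                sprintf("LIN at line %d references a residue outside its block",
                        l$line))
    }
    childIdxs <- vapply(b$lin, `[[`, integer(1), "child")
    if (anyDuplicated(childIdxs))
      glyStop("glycoctReferenceError", "a residue is linked to two parents")
    rootCandidates <- resIdx[kinds != "s" & !(resIdx %in% childIdxs)]
    orphanSubs <- resIdx[kinds == "s" & !(resIdx %in% childIdxs)]
    if (length(orphanSubs))
      glyStop("glycoctReferenceError", "unlinked substituent entry")
    if (length(rootCandidates) != 1L)
      glyStop("glycoctReferenceError",
              sprintf("expected exactly one root residue, found %d",
                      length(rootCandidates)))
    rootIdx <- rootCandidates[[1]]

    subsOf <- function(idx) Filter(function(l)
      l$child %in% resIdx[kinds == "s"] && l$parent == idx, b$lin)
    glycChildren <- function(idx) Filter(function(l)
      byIdx[[as.character(l$child)]]$kind != "s" && l$parent == idx, b$lin)

    makeResidue <- function(idx) {
      entry <- byIdx[[as.character(idx)]]
      if (entry$kind == "r") {
        k <- sub("^r", "", entry$desc)
        rb <- repBlocks[[k]]
        if (is.null(rb))
          glyStop("glycoctReferenceError",
                  sprintf("missing REP block %s", k))
        key <- paste0("rep", k)
        if (is.null(built[[key]])) built[[key]] <- buildBlock(rb)
        bb <- built[[key]]
        if (bb$rootIdx != rb$rootIdx)
          glyStop("glycoctReferenceError", "REP root index mismatch")
        leafNode <- bb$idMap[[as.character(rb$leafIdx)]]
        if (is.null(leafNode))
          glyStop("glycoctReferenceError", "REP leaf index not in its block")
        return(list(kind = "rep",
                    unit = repeatUnit(bb$glycan, rb$minCount, rb$maxCount,
                                      linkage(rb$donPos, rb$accPos),
                                      acceptorNodeId = leafNode)))
      }
      if (entry$kind != "b")
        .parseError(entry$line, "substituent cannot be a parent residue")
      p <- parseMono(entry)
      subs <- lapply(subsOf(idx), function(l) {
        sdesc <- byIdx[[as.character(l$child)]]$desc
        .getSubType(sdesc)  # vocabulary check -> error if unknown
        if (l$ctype != "n")
          .parseError(l$line, "substituent linkage must end in 'n'")
        if (length(l$acc) > 1L)
          .parseError(l$line,
                      "alternative positions are not supported on substituents")
        list(stype = sdesc, pos = l$acc, ptype = l$ptype)
      })
      ## amino-sugar fusion: amino@p (d-link) or N-acyl@p (d-link) upgrade the
      ## basetype to its amine variant at p
      amap <- .vocabGet("amineMap")
      keepSubs <- rep(TRUE, length(subs))
      type <- p$type
      for (si in seq_along(subs)) {
        s <- subs[[si]]
        if (is.na(s$pos) || s$ptype != "d") next
        variant <- amap[[paste(type, s$pos, sep = "@")]]
        if (is.null(variant)) next
        if (s$stype == "amino") {
          type <- variant; keepSubs[si] <- FALSE
        } else if (s$stype %in% c("n-acetyl", "n-glycolyl")) {
          type <- variant  # keep the acyl substituent, now on the amine
        }
      }
      list(kind = "mono", p = p, type = type, subs = subs[keepSubs])
    }

    idMap <- list()
    g <- NULL
    attachTree <- function(idx, parentNodeId) {
      r <- makeResidue(idx)
      if (r$kind == "rep") {
        if (is.null(parentNodeId)) {
          g <<- createGlycan(r$unit)
        } else {
          l <- linkEdge(idx)
          g <<- addRepeatUnit(g, parentNodeId, r$unit,
                              linkage(l$don, l$acc))
        }
      } else {
        nd <- monosaccharide(r$type, r$p$anomericity,
                             ring = r$p$ring, config = r$p$config)
        if (is.null(parentNodeId)) {
          g <<- createGlycan(nd)
        } else {
          l <- linkEdge(idx)
          g <<- addMonosaccharide(g, parentNodeId, nd, linkage(l$don, l$acc))
        }
        myId <- lastNodeId(g)
        for (s in r$subs)
          g <<- addSubstituent(g, myId, substituent(s$stype), s$pos)
        idMap[[as.character(idx)]] <<- myId
        for (l in glycChildren(idx)) attachTree(l$child, myId)
        return(invisible(NULL))
      }
      myId <- lastNodeId(g)
      idMap[[as.character(idx)]] <<- myId
      for (l in glycChildren(idx)) attachTree(l$child, myId)
      invisible(NULL)
    }
    linkEdge <- function(idx) {
      for (l in b$lin) if (l$child == idx) {
        if (l$ptype != "o" && l$ptype != "d")
          .parseError(l$line, "unexpected glycosidic link type")
        return(list(don = l$don, acc = l$acc))
      }
      glyStop("glycoctReferenceError", "missing linkage for residue")
    }
    attachTree(rootIdx, NULL)
    list(glycan = g, idMap = idMap, rootIdx = rootIdx)
  }

  top <- blocks[[1]]
  if (!length(top$res)) glyStop("glycoctParseError", "RES section is empty")
  buildBlock(top)$glycan
}

#' Canonical normal form of a GlycoCT document
#'
#' Parse-then-write fixpoint representative: idempotent, insensitive to line
#' endings and to the order of LIN entries describing the same structure.
#'
#' @param text GlycoCT condensed text (or path).
#' @return Canonical GlycoCT text.
#' @export
normalizeGlycoCT <- function(text) writeGlycoCT(parseGlycoCT(text))
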