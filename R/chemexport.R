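## Chemical export of fully defined glycans. Each residue is instantiated
## from its ring-form atom template (carbons, ring oxygen, hydroxyls, chain
## modifications, amine); each glycosidic bond is formed by condensation:
## the donor's anomeric hydroxyl is removed and its anomeric carbon bonds to
## the acceptor-side oxygen, so one water is lost per edge and the
## glycosidic oxygen belongs to the acceptor. Substituents attach via their
## mode (O-linked groups keep the position oxygen; N-linked groups replace
## it). Charged substituents are emitted in neutral protonated form.

#' MolecularGraph: atoms and bonds of an expanded glycan
#'
#' Hydrogens are implicit: each heavy atom carries an \code{hcount} filling
#' its standard valence (C 4, N 3, O 2, S 6, P 5). \code{nodeId} maps each
#' atom back to the residue (of the repeat-expanded glycan) it came from.
#'
#' @slot atoms data.frame: element, charge, stereo, hcount, nodeId.
#' @slot bonds data.frame: atom1, atom2, order.
#' @slot start Index of the reducing-end anomeric carbon.
#' @export
setClass("MolecularGraph",
         representation(atoms = "data.frame", bonds = "data.frame",
                        start = "integer"))

#' @rdname MolecularGraph-class
#' @param object A MolecularGraph.
#' @export
setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d heavy atoms, %d bonds, formula %s\n",
              nrow(object@atoms), nrow(object@bonds), graphFormula(object)))
})

#' @rdname MolecularGraph-class
#' @param mg A MolecularGraph.
#' @param includeH Count implicit hydrogens too?
#' @export
atomCount <- function(mg, includeH = TRUE) {
  nrow(mg@atoms) + if (includeH) sum(mg@atoms$hcount) else 0L
}

#' @rdname MolecularGraph-class
#' @export
graphFormula <- function(mg) {
  counts <- table(mg@atoms$element)
  f <- .zeroFormula()
  f[names(counts)] <- counts
  f["H"] <- sum(mg@atoms$hcount)
  formulaString(f)
}

.chemGate <- function(g) {
  if (glycanSize(g) == 0L)
    glyStop("glycanEmptyError", "empty glycan has no chemical structure")
  if (!isFullyDefined(g))
    glyStop("glycanUnderdeterminedError",
            "chemical export is restricted to fully defined structures")
}

## Replace repeat units by min==max chained copies. Copy i+1's root donates
## to copy i's acceptor leaf; host children of the repeat reattach to the
## last copy's acceptor leaf.
.expandRepeats <- function(g) {
  if (!any(vapply(g@nodes, is, logical(1), "RepeatUnit"))) return(g)
  out <- NULL
  lastIdOf <- function() if (is.null(out)) 0L else lastNodeId(out)

  attachNode <- function(srcId, parentOutId, lnk) {
    nd <- g@nodes[[as.character(srcId)]]
    if (is(nd, "Substituent")) {
      a <- lnk@acceptors
      out <<- addSubstituent(out, parentOutId, substituent(nd@stype),
                             if (length(a) == 1L) a else NA_integer_)
      return(invisible(NULL))
    }
    if (is(nd, "Monosaccharide")) {
      if (is.null(parentOutId)) out <<- createGlycan(nd)
      else out <<- addMonosaccharide(out, parentOutId, nd, lnk)
      myId <- lastIdOf()
      for (e in .orderChildEdges(g, srcId)) attachNode(e$child, myId, e$linkage)
      return(invisible(NULL))
    }
    ## repeat unit
    count <- nd@minCount
    if (is.na(count) || is.na(nd@maxCount) || count != nd@maxCount)
      glyStop("glycanUnderdeterminedError",
              "repeat unit with ambiguous copy count cannot be expanded")
    if (any(vapply(nd@internal@nodes, is, logical(1), "RepeatUnit")))
      glyStop("glycanUnderdeterminedError",
              "nested repeat units are not supported for chemical export")
    frag <- copySubtree(nd@internal, nd@internal@rootId)
    srcOrder <- .descendants(nd@internal, nd@internal@rootId)
    leafSrc <- if (!is.na(nd@acceptorNodeId)) nd@acceptorNodeId
               else .canonicalLastLeaf(nd@internal)
    leafOffset <- match(leafSrc, srcOrder)
    prevLeaf <- NULL
    for (i in seq_len(count)) {
      before <- lastIdOf()
      if (i == 1L && is.null(parentOutId)) {
        out <<- frag
      } else if (i == 1L) {
        out <<- pasteSubtree(out, parentOutId, frag, lnk)
      } else {
        out <<- pasteSubtree(out, prevLeaf, frag, nd@internalLinkage)
      }
      prevLeaf <- before + leafOffset
    }
    for (e in .orderChildEdges(g, srcId)) attachNode(e$child, prevLeaf, e$linkage)
    invisible(NULL)
  }
  attachNode(g@rootId, NULL, NULL)
  out
}

## acyl / O-linked group expansion tables used by the graph builder
.groupAtoms <- function(stype) {
  switch(stype,
    methyl = list(el = "C", bonds = list(), anchor = 1L),
    acetyl = list(el = c("C", "O", "C"),
                  bonds = list(c(1L, 2L, 2L), c(1L, 3L, 1L)), anchor = 1L),
    `n-acetyl` = list(el = c("C", "O", "C"),
                      bonds = list(c(1L, 2L, 2L), c(1L, 3L, 1L)), anchor = 1L),
    `n-glycolyl` = list(el = c("C", "O", "C", "O"),
                        bonds = list(c(1L, 2L, 2L), c(1L, 3L, 1L),
                                     c(3L, 4L, 1L)), anchor = 1L),
    sulfate = list(el = c("S", "O", "O", "O"),
                   bonds = list(c(1L, 2L, 2L), c(1L, 3L, 2L), c(1L, 4L, 1L)),
                   anchor = 1L),
    phosphate = list(el = c("P", "O", "O", "O"),
                     bonds = list(c(1L, 2L, 2L), c(1L, 3L, 1L), c(1L, 4L, 1L)),
                     anchor = 1L),
    pyruvate = list(el = c("C", "O", "C", "O", "C"),
                    bonds = list(c(1L, 2L, 2L), c(1L, 3L, 1L),
                                 c(3L, 4L, 2L), c(3L, 5L, 1L)), anchor = 1L),
    glyStop("chemExportError",
            sprintf("no atom template for substituent '%s'", stype)))
}

.stdValence <- c(C = 4L, N = 3L, O = 2L, S = 6L, P = 5L)

#' Expand a fully defined glycan into a molecular graph
#'
#' @param g A non-empty, fully defined \linkS4class{Glycan}. Repeat units
#'   must have a determinate copy count (minCount == maxCount).
#' @return A \linkS4class{MolecularGraph}.
#' @export
#' @examples
#' mg <- toMolecularGraph(createGlycan(monosaccharide("Glc", "beta")))
#' atomCount(mg)      # 24 (C6H12O6)
#' graphFormula(mg)   # "C6H12O6"
toMolecularGraph <- function(g) {
  .chemGate(g)
  g <- .expandRepeats(g)

  el <- character(0); stereoV <- character(0); nodeV <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bo <- integer(0)
  addAtom <- function(e, node) {
    el <<- c(el, e); stereoV <<- c(stereoV, ""); nodeV <<- c(nodeV, node)
    length(el)
  }
  addBond <- function(i, j, order = 1L) {
    b1 <<- c(b1, i); b2 <<- c(b2, j); bo <<- c(bo, order)
  }

  linkO <- list()     # nodeId -> position -> oxygen index for attachment
  carbonOf <- list()  # nodeId -> position -> carbon index
  amineOf <- list()   # nodeId -> nitrogen index
  ringInfo <- list()  # nodeId -> c(anomeric, closure) or NULL

  ## per-residue attachment plan gathered from edges
  parentEdgeOf <- function(id) {
    for (e in g@edges) if (e$child == id) return(e)
    NULL
  }
  subsAt <- function(id) {
    out <- list()
    for (e in .childEdges(g, id)) {
      kid <- g@nodes[[as.character(e$child)]]
      if (is(kid, "Substituent"))
        out[[length(out) + 1L]] <- list(stype = kid@stype,
                                        pos = e$linkage@acceptors[1])
    }
    out
  }

  for (idc in names(g@nodes)) {
    nd <- g@nodes[[idc]]
    if (!is(nd, "Monosaccharide")) next
    id <- nd@nodeId
    mt <- .getMonoType(nd@mtype)
    cc <- mt$carbon_count; ac <- mt$anomeric_carbon
    mods <- .monoMods(nd@mtype)
    modAt <- structure(sub("^[0-9]+:", "", mods),
                       names = sub(":.*$", "", mods))
    closure <- switch(nd@ring, pyranose = ac + 4L, furanose = ac + 3L,
                      NA_integer_)
    donorUsed <- !is.null(parentEdgeOf(id))
    subPlan <- subsAt(id)
    subPos <- vapply(subPlan, function(s)
      if (is.na(s$pos)) -1L else as.integer(s$pos), integer(1))
    dModeAt <- function(p) {
      for (s in subPlan)
        if (!is.na(s$pos) && s$pos == p &&
            .getSubType(s$stype)$mode == "d" &&
            (is.na(mt$amine_position) || p != mt$amine_position))
          return(TRUE)
      FALSE
    }

    C <- integer(cc)
    for (p in seq_len(cc)) C[p] <- addAtom("C", id)
    for (p in seq_len(cc - 1L)) addBond(C[p], C[p + 1L])
    lo <- rep(NA_integer_, cc)

    if (!is.na(closure)) {
      ringO <- addAtom("O", id)
      addBond(C[ac], ringO); addBond(C[closure], ringO)
    }
    for (p in seq_len(cc)) {
      pc <- as.character(p)
      mod <- if (pc %in% names(modAt)) modAt[[pc]] else ""
      if (!is.na(mt$amine_position) && p == mt$amine_position) {
        N <- addAtom("N", id); addBond(C[p], N)
        amineOf[[idc]] <- N
        next
      }
      if (mod == "d") next
      if (mod == "a") {
        Od <- addAtom("O", id); addBond(C[p], Od, 2L)
        Oh <- addAtom("O", id); addBond(C[p], Oh)
        lo[p] <- Oh
        next
      }
      if (!is.na(closure) && p == closure) next
      if (p == ac) {
        if (is.na(closure)) {           # open chain: carbonyl
          Od <- addAtom("O", id); addBond(C[p], Od, 2L)
        } else if (!donorUsed) {        # free anomeric hydroxyl
          Oh <- addAtom("O", id); addBond(C[p], Oh)
          lo[p] <- Oh
        }                               # donor: bonds to the acceptor oxygen
        next
      }
      if (dModeAt(p)) {                 # N-linked substituent replaces the OH
        N <- addAtom("N", id); addBond(C[p], N)
        lo[p] <- -N                     # negative marks a nitrogen anchor
        next
      }
      Oh <- addAtom("O", id); addBond(C[p], Oh)
      lo[p] <- Oh
    }
    carbonOf[[idc]] <- C
    linkO[[idc]] <- lo
    ringInfo[[idc]] <- if (is.na(closure)) NULL else c(ac, closure)
  }

  ## glycosidic condensation bonds
  for (e in g@edges) {
    kid <- g@nodes[[as.character(e$child)]]
    if (!is(kid, "Monosaccharide")) next
    pid <- as.character(e$parent)
    ap <- e$linkage@acceptors[1]
    anchor <- linkO[[pid]][ap]
    if (is.na(anchor) || anchor < 0L)
      glyStop("chemExportError",
              sprintf("no attachment oxygen at position %d of node %s", ap, pid))
    addBond(carbonOf[[as.character(e$child)]][.anomericCarbon(kid@mtype)],
            anchor)
  }

  ## substituent groups
  for (e in g@edges) {
    kid <- g@nodes[[as.character(e$child)]]
    if (!is(kid, "Substituent")) next
    pid <- as.character(e$parent)
    parent <- g@nodes[[pid]]
    p <- e$linkage@acceptors[1]
    mt <- .getMonoType(parent@mtype)
    if (kid@stype == "amino") next  # nitrogen already placed in the template
    onAmine <- !is.na(mt$amine_position) && !is.na(p) && p == mt$amine_position
    anchor <- if (onAmine) amineOf[[pid]]
      else {
        a <- linkO[[pid]][p]
        if (is.na(a))
          glyStop("chemExportError",
                  sprintf("no attachment point at position %d of node %s", p, pid))
        abs(a)
      }
    grp <- .groupAtoms(kid@stype)
    idxs <- vapply(grp$el, function(ee) addAtom(ee, kid@nodeId), integer(1))
    for (bd in grp$bonds) addBond(idxs[bd[1]], idxs[bd[2]], bd[3])
    addBond(anchor, idxs[grp$anchor])
  }

  ## implicit hydrogen fill
  val <- integer(length(el))
  for (i in seq_along(b1)) {
    val[b1[i]] <- val[b1[i]] + bo[i]
    val[b2[i]] <- val[b2[i]] + bo[i]
  }
  hcount <- .stdValence[el] - val
  if (any(hcount < 0))
    glyStop("chemExportError", "valence overflow in expansion")

  ## ring stereocentre markers: deterministic per type/position convention,
  ## flipped by anomericity at the anomeric carbon and by configuration at
  ## the ring-closure carbon
  hasDouble <- unique(c(b1[bo == 2L], b2[bo == 2L]))
  for (idc in names(ringInfo)) {
    ri <- ringInfo[[idc]]
    if (is.null(ri)) next
    nd <- g@nodes[[idc]]
    C <- carbonOf[[idc]]
    for (p in ri[1]:ri[2]) {
      a <- C[p]
      if (hcount[a] > 1L || a %in% hasDouble) next
      bit <- p %% 2L == 0L
      if (p == ri[1] && nd@anomericity == "alpha") bit <- !bit
      if (p == ri[2] && nd@config == "L") bit <- !bit
      stereoV[a] <- if (bit) "@" else "@@"
    }
  }

  rootNd <- g@nodes[[as.character(g@rootId)]]
  start <- carbonOf[[as.character(g@rootId)]][.anomericCarbon(rootNd@mtype)]
  new("MolecularGraph",
      atoms = data.frame(element = el, charge = 0L, stereo = stereoV,
                         hcount = as.integer(hcount), nodeId = nodeV,
                         stringsAsFactors = FALSE),
      bonds = data.frame(atom1 = b1, atom2 = b2, order = bo),
      start = as.integer(start))
}

#' Molecular formula of a fully defined glycan
#'
#' Computed by the condensation law: the sum of the residue formula
#' templates plus substituent deltas, minus one water per glycosidic edge.
#' Equal to the formula of the full atomistic expansion
#' (\code{graphFormula(toMolecularGraph(g))}).
#'
#' @param g A non-empty, fully defined \linkS4class{Glycan}.
#' @param counts Return the named element-count vector instead of the Hill
#'   string?
#' @return Hill-order formula string (or named vector).
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("Glc", "beta"))
#' molecularFormula(g)  # "C6H12O6"
molecularFormula <- function(g, counts = FALSE) {
  .chemGate(g)
  g <- .expandRepeats(g)
  f <- .zeroFormula()
  nEdges <- 0L
  for (nd in g@nodes)
    if (is(nd, "Monosaccharide")) f <- .addFormula(f, .monoFormula(nd@mtype))
  for (e in g@edges) {
    kid <- g@nodes[[as.character(e$child)]]
    if (is(kid, "Monosaccharide")) { nEdges <- nEdges + 1L; next }
    parent <- g@nodes[[as.character(e$parent)]]
    mt <- .getMonoType(parent@mtype)
    p <- e$linkage@acceptors[1]
    ctx <- if (!is.na(mt$amine_position) && !is.na(p) &&
               p == mt$amine_position &&
               kid@stype %in% c("n-acetyl", "n-glycolyl")) "amine"
           else "hydroxyl"
    f <- .addFormula(f, .subDelta(kid@stype, ctx))
  }
  f <- .addFormula(f, c(H = -2 * nEdges, O = -nEdges))
  if (counts) f else formulaString(f)
}

#' SMILES export of a fully defined glycan
#'
#' Depth-first emission over the molecular graph starting at the
#' reducing-end anomeric carbon; ring closures use numbered bonds and ring
#' stereocentres carry tetrahedral markers. Deterministic: identical glycans
#' give identical strings. Neutral protonated form for acidic substituents.
#'
#' @param g A non-empty, fully defined \linkS4class{Glycan}.
#' @return A SMILES string.
#' @export
#' @examples
#' toSMILES(createGlycan(monosaccharide("Glc", "beta")))
toSMILES <- function(g) {
  mg <- toMolecularGraph(g)
  n <- nrow(mg@atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mg@bonds))) {
    a <- mg@bonds$atom1[i]; b <- mg@bonds$atom2[i]; o <- mg@bonds$order[i]
    adj[[a]] <- c(adj[[a]], list(c(b, o)))
    adj[[b]] <- c(adj[[b]], list(c(a, o)))
  }
  visited <- logical(n)
  treeKids <- vector("list", n)
  closures <- vector("list", n)   # per atom: list of c(digit, order)
  digit <- 0L
  openSet <- new.env(parent = emptyenv())

  ## iterative DFS to classify tree vs ring-closure bonds
  stack <- list(c(mg@start, 0L))
  visited[mg@start] <- TRUE
  order_ <- function(x) x  # clarity no-op
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- top[1]; parent <- top[2]
    for (nb in adj[[a]]) {
      b <- nb[1]; o <- nb[2]
      if (b == parent) { parent <- -1L; next }  # consume one parent edge
      key <- paste(min(a, b), max(a, b))
      if (!is.null(openSet[[key]])) next
      if (visited[b]) {
        openSet[[key]] <- TRUE
        digit <- digit + 1L
        closures[[a]] <- c(closures[[a]], list(c(digit, o)))
        closures[[b]] <- c(closures[[b]], list(c(digit, o)))
      } else {
        visited[b] <- TRUE
        openSet[[key]] <- TRUE
        treeKids[[a]] <- c(treeKids[[a]], list(c(b, o)))
        stack[[length(stack) + 1L]] <- c(b, a)
      }
    }
  }

  digitToken <- function(d) if (d < 10L) as.character(d) else sprintf("%%%d", d)
  bondToken <- function(o) if (o == 2L) "=" else ""
  atomToken <- function(i) {
    e <- mg@atoms$element[i]; st <- mg@atoms$stereo[i]; h <- mg@atoms$hcount[i]
    if (st == "") return(e)
    hpart <- if (h == 0L) "" else if (h == 1L) "H" else sprintf("H%d", h)
    sprintf("[%s%s%s]", e, st, hpart)
  }
  emit <- function(i) {
    out <- atomToken(i)
    for (cl in closures[[i]])
      out <- paste0(out, bondToken(cl[2]), digitToken(cl[1]))
    kids <- treeKids[[i]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        kid <- kids[[k]]
        part <- paste0(bondToken(kid[2]), emit(kid[1]))
        out <- paste0(out, if (k < length(kids)) paste0("(", part, ")")
                           else part)
      }
    }
    out
  }
  emit(mg@start)
}
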