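## Structural editing operations on Glycan trees. All operations are
## functional: they return the modified glycan and never touch their input.
## The id of the most recently inserted node is available via lastNodeId().

#' Create a glycan from its reducing-end residue
#'
#' @param root A \linkS4class{Monosaccharide} or \linkS4class{RepeatUnit}
#'   built from the controlled vocabularies.
#' @return A \linkS4class{Glycan} with one node and no edges.
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("GlcN", "beta"))
#' glycanSize(g)
createGlycan <- function(root) {
  if (!is(root, "Monosaccharide") && !is(root, "RepeatUnit"))
    glyStop("glycanVocabularyError",
            "root must be a Monosaccharide or RepeatUnit")
  v <- validObject(root, test = TRUE)
  if (!isTRUE(v)) glyStop("glycanInvariantError", v)
  root@nodeId <- 1L
  g <- new("Glycan", nodes = structure(list(root), names = "1"),
           edges = list(), rootId = 1L, counter = 1L)
  .checkGlycan(g)
}

#' @rdname createGlycan
#' @export
emptyGlycan <- function()
  new("Glycan", nodes = list(), edges = list(),
      rootId = NA_integer_, counter = 0L)

.checkGlycan <- function(g) {
  v <- .glycanValidity(g)
  if (!isTRUE(v)) glyStop("glycanInvariantError", v)
  g
}

.node <- function(g, id) {
  nd <- g@nodes[[as.character(id)]]
  if (is.null(nd))
    glyStop("glycanMissingNodeError", sprintf("no node with id %s", id))
  nd
}

#' Glycan accessors
#'
#' \code{glycanSize} counts nodes; \code{nodeIds} lists ids;
#' \code{getNode} fetches one node; \code{glycanRoot} returns the root id;
#' \code{lastNodeId} returns the id most recently handed out (the id of the
#' node added by the last insertion operation); \code{childIds} and
#' \code{parentId} navigate edges; \code{edgeLinkage} returns the
#' \linkS4class{GlycosidicLinkage} above a child node.
#'
#' @param g A \linkS4class{Glycan}.
#' @param id A node id.
#' @return See individual descriptions.
#' @export
glycanSize <- function(g) length(g@nodes)

#' @rdname glycanSize
#' @export
nodeIds <- function(g) as.integer(names(g@nodes))

#' @rdname glycanSize
#' @export
getNode <- function(g, id) .node(g, id)

#' @rdname glycanSize
#' @export
glycanRoot <- function(g) g@rootId

#' @rdname glycanSize
#' @export
lastNodeId <- function(g) g@counter

#' @rdname glycanSize
#' @export
childIds <- function(g, id)
  vapply(Filter(function(e) e$parent == id, g@edges),
         function(e) e$child, integer(1))

#' @rdname glycanSize
#' @export
parentId <- function(g, id) {
  for (e in g@edges) if (e$child == id) return(e$parent)
  NA_integer_
}

#' @rdname glycanSize
#' @export
edgeLinkage <- function(g, id) {
  for (e in g@edges) if (e$child == id) return(e$linkage)
  NULL
}

.childEdges <- function(g, id) Filter(function(e) e$parent == id, g@edges)

.statedGlycosidicPositions <- function(g, parentId) {
  unlist(lapply(.childEdges(g, parentId), function(e) {
    if (is(g@nodes[[as.character(e$child)]], "Substituent")) return(integer(0))
    a <- e$linkage@acceptors
    if (length(a) == 1L && !is.na(a)) a else integer(0)
  }))
}

.insert <- function(g, parentId, node, lnk) {
  id <- g@counter + 1L
  node@nodeId <- id
  g@nodes[[as.character(id)]] <- node
  g@edges[[length(g@edges) + 1L]] <- list(parent = as.integer(parentId),
                                          child = id, linkage = lnk)
  g@counter <- id
  g
}

#' Attach a monosaccharide to an existing residue
#'
#' Adds one node and one edge. A fully-stated acceptor position already
#' occupied by another glycosidic child raises an attachment conflict;
#' attaching to a substituent is illegal.
#'
#' @param g A \linkS4class{Glycan}.
#' @param parentId Id of the parent residue.
#' @param residue A \linkS4class{Monosaccharide}.
#' @param lnk A \linkS4class{GlycosidicLinkage}.
#' @return The extended glycan; the new node's id is \code{lastNodeId()}.
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("Glc", "beta"))
#' g <- addMonosaccharide(g, 1, monosaccharide("Gal", "beta"), linkage(1, 4))
addMonosaccharide <- function(g, parentId, residue, lnk) {
  parent <- .node(g, parentId)
  if (is(parent, "Substituent"))
    glyStop("glycanIllegalParentError",
            "cannot attach a residue to a substituent")
  v <- validObject(residue, test = TRUE)
  if (!isTRUE(v)) glyStop("glycanInvariantError", v)
  v <- validObject(lnk, test = TRUE)
  if (!isTRUE(v)) glyStop("glycanRangeError", v)
  if (is(parent, "Monosaccharide")) {
    cc <- .carbonCount(parent@mtype)
    if (any(!is.na(lnk@acceptors) & lnk@acceptors > cc))
      glyStop("glycanRangeError",
              sprintf("acceptor position beyond carbon %d of %s", cc, parent@mtype))
  }
  if (!is.na(lnk@donor) && lnk@donor > .carbonCount(residue@mtype))
    glyStop("glycanRangeError", "donor position beyond residue carbon count")
  a <- lnk@acceptors
  if (length(a) == 1L && !is.na(a) &&
      a %in% .statedGlycosidicPositions(g, parentId))
    glyStop("glycanConflictError",
            sprintf("position %d of node %s is already occupied", a, parentId))
  .checkGlycan(.insert(g, parentId, residue, lnk))
}

#' Attach a substituent to a residue
#'
#' Adds a childless decoration node (N-acetyl, sulfate, ...) at a carbon
#' position of a monosaccharide. Position NA records an UNKNOWN attachment.
#'
#' @param g A \linkS4class{Glycan}.
#' @param parentId Id of the parent monosaccharide.
#' @param sub A \linkS4class{Substituent}.
#' @param position Integer carbon position or NA.
#' @return The extended glycan; new id via \code{lastNodeId()}.
#' @details Amino-group chemistry is canonicalized on attachment: adding
#'   \code{n-acetyl}/\code{n-glycolyl} at a position where the parent type
#'   has an amine-bearing variant (e.g. position 2 of Glc) upgrades the
#'   parent to that variant (GlcN) with the acyl group on its nitrogen, and
#'   adding \code{amino} there performs the upgrade alone without creating a
#'   node. This keeps the model form of amino sugars unique, matching their
#'   single-s-entry GlycoCT encoding.
#' @export
addSubstituent <- function(g, parentId, sub, position) {
  parent <- .node(g, parentId)
  if (!is(parent, "Monosaccharide"))
    glyStop("glycanIllegalParentError",
            "substituents attach to monosaccharides only")
  position <- as.integer(position)
  if (!is.na(position)) {
    cc <- .carbonCount(parent@mtype)
    if (position < 1L || position > cc)
      glyStop("glycanRangeError",
              sprintf("position %d outside 1..%d of %s", position, cc, parent@mtype))
    occupied <- unlist(lapply(.childEdges(g, parentId), function(e) {
      if (!is(g@nodes[[as.character(e$child)]], "Substituent")) return(integer(0))
      a <- e$linkage@acceptors
      if (length(a) == 1L && !is.na(a)) a else integer(0)
    }))
    if (position %in% occupied)
      glyStop("glycanConflictError",
              sprintf("substituent position %d already occupied", position))
  }
  if (!is.na(position) &&
      sub@stype %in% c("amino", "n-acetyl", "n-glycolyl")) {
    variant <- .vocabGet("amineMap")[[paste(parent@mtype, position, sep = "@")]]
    if (!is.null(variant)) {
      parent@mtype <- variant
      g@nodes[[as.character(parentId)]] <- parent
      if (sub@stype == "amino") return(.checkGlycan(g))
    }
  }
  .checkGlycan(.insert(g, parentId, sub, linkage(1L, position)))
}

.descendants <- function(g, id) {
  out <- integer(0); queue <- as.integer(id)
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    out <- c(out, x)
    queue <- c(queue, childIds(g, x))
  }
  out
}

#' Remove a node and its whole subtree
#'
#' Remaining ids are unchanged; removing the root yields the empty glycan.
#'
#' @param g A \linkS4class{Glycan}.
#' @param id Node id to prune.
#' @return The pruned glycan.
#' @export
removeSubtree <- function(g, id) {
  .node(g, id)
  if (id == g@rootId) {
    e <- emptyGlycan(); e@counter <- g@counter
    return(e)
  }
  drop <- .descendants(g, id)
  g@nodes <- g@nodes[!names(g@nodes) %in% as.character(drop)]
  g@edges <- Filter(function(e) !(e$child %in% drop) && !(e$parent %in% drop),
                    g@edges)
  .checkGlycan(g)
}

#' Update fields of a monosaccharide in place
#'
#' Semantic replacement with unchanged topology. Changing the type to one
#' whose carbon count falls below an existing linkage position is a
#' consistency error.
#'
#' @param g A \linkS4class{Glycan}.
#' @param id Node id of a monosaccharide.
#' @param mtype,anomericity,ring,config Fields to change (NULL = keep).
#' @return The updated glycan.
#' @export
updateNode <- function(g, id, mtype = NULL, anomericity = NULL,
                       ring = NULL, config = NULL) {
  nd <- .node(g, id)
  if (!is(nd, "Monosaccharide"))
    glyStop("glycanInvariantError", "only monosaccharide nodes can be updated")
  if (!is.null(mtype)) { .getMonoType(mtype); nd@mtype <- mtype }
  if (!is.null(anomericity)) nd@anomericity <- anomericity
  if (!is.null(ring)) nd@ring <- ring
  if (!is.null(config)) nd@config <- config
  v <- validObject(nd, test = TRUE)
  if (!isTRUE(v)) glyStop("glycanInvariantError", v)
  cc <- .carbonCount(nd@mtype)
  for (e in g@edges) {
    if (e$parent == id) {
      a <- e$linkage@acceptors
      if (any(!is.na(a) & a > cc))
        glyStop("glycanConsistencyError",
                sprintf("existing child linkage exceeds carbon count %d", cc))
    }
    if (e$child == id && !is.na(e$linkage@donor) && e$linkage@donor > cc)
      glyStop("glycanConsistencyError",
              sprintf("existing donor position exceeds carbon count %d", cc))
  }
  g@nodes[[as.character(id)]] <- nd
  .checkGlycan(g)
}

#' Copy and paste subtrees
#'
#' \code{copySubtree} deep-copies the subtree rooted at \code{id} into a
#' standalone glycan fragment with fresh ids (root id 1);
#' \code{pasteSubtree} grafts such a fragment under a parent, renumbering
#' its nodes to fresh ids (the pasted root becomes
#' \code{lastNodeId(g) + 1} of the input glycan). The source is untouched.
#'
#' @param g A \linkS4class{Glycan}.
#' @param id Root of the subtree to copy.
#' @return \code{copySubtree}: a \linkS4class{Glycan} fragment.
#' @export
copySubtree <- function(g, id) {
  .node(g, id)
  keep <- .descendants(g, id)
  remap <- structure(seq_along(keep), names = as.character(keep))
  nodes <- list()
  for (old in keep) {
    nd <- g@nodes[[as.character(old)]]
    nd@nodeId <- unname(remap[as.character(old)])
    nodes[[as.character(nd@nodeId)]] <- nd
  }
  edges <- lapply(Filter(function(e) e$parent %in% keep && e$child %in% keep,
                         g@edges), function(e)
    list(parent = unname(remap[as.character(e$parent)]),
         child = unname(remap[as.character(e$child)]),
         linkage = e$linkage))
  .checkGlycan(new("Glycan", nodes = nodes, edges = edges,
                   rootId = 1L, counter = length(keep)))
}

#' @rdname copySubtree
#' @param parentId Attachment parent in \code{g}.
#' @param fragment A fragment from \code{copySubtree}.
#' @param lnk \linkS4class{GlycosidicLinkage} for the graft.
#' @export
pasteSubtree <- function(g, parentId, fragment, lnk) {
  parent <- .node(g, parentId)
  if (is(parent, "Substituent"))
    glyStop("glycanIllegalParentError",
            "cannot attach a residue to a substituent")
  fragRoot <- fragment@nodes[[as.character(fragment@rootId)]]
  a <- lnk@acceptors
  if (is(parent, "Monosaccharide")) {
    cc <- .carbonCount(parent@mtype)
    if (any(!is.na(a) & a > cc))
      glyStop("glycanRangeError", "acceptor position beyond parent carbon count")
  }
  if (length(a) == 1L && !is.na(a) &&
      a %in% .statedGlycosidicPositions(g, parentId))
    glyStop("glycanConflictError",
            sprintf("position %d of node %s is already occupied", a, parentId))
  ## insert fragment nodes in preorder so the pasted root gets the first id
  order <- .descendants(fragment, fragment@rootId)
  remap <- structure(g@counter + seq_along(order), names = as.character(order))
  for (old in order) {
    nd <- fragment@nodes[[as.character(old)]]
    nd@nodeId <- unname(remap[as.character(old)])
    g@nodes[[as.character(nd@nodeId)]] <- nd
  }
  g@edges[[length(g@edges) + 1L]] <-
    list(parent = as.integer(parentId),
         child = unname(remap[as.character(fragment@rootId)]), linkage = lnk)
  for (e in fragment@edges)
    g@edges[[length(g@edges) + 1L]] <-
      list(parent = unname(remap[as.character(e$parent)]),
           child = unname(remap[as.character(e$child)]), linkage = e$linkage)
  g@counter <- g@counter + length(order)
  .checkGlycan(g)
}

#' Attach a repeating unit as a single host-tree node
#'
#' @param g A \linkS4class{Glycan}.
#' @param parentId Parent residue id.
#' @param unit A \linkS4class{RepeatUnit}.
#' @param lnk \linkS4class{GlycosidicLinkage} to the host parent.
#' @return The extended glycan.
#' @export
addRepeatUnit <- function(g, parentId, unit, lnk) {
  parent <- .node(g, parentId)
  if (is(parent, "Substituent"))
    glyStop("glycanIllegalParentError",
            "cannot attach a repeat unit to a substituent")
  v <- validObject(unit, test = TRUE)
  if (!isTRUE(v)) glyStop("glycanRangeError", v)
  a <- lnk@acceptors
  if (length(a) == 1L && !is.na(a) &&
      a %in% .statedGlycosidicPositions(g, parentId))
    glyStop("glycanConflictError",
            sprintf("position %d of node %s is already occupied", a, parentId))
  .checkGlycan(.insert(g, parentId, unit, lnk))
}

#' Is a glycan fully defined?
#'
#' TRUE iff the structure carries no UNKNOWN position, no multi-alternative
#' acceptor set, no undetermined anomericity, ring form or absolute
#' configuration anywhere (including inside repeat units), and no repeat
#' unit with UNKNOWN counts. Chemical-format export requires this.
#'
#' @param g A \linkS4class{Glycan}.
#' @return logical(1).
#' @export
#' @examples
#' isFullyDefined(createGlycan(monosaccharide("Glc", "beta")))
#' isFullyDefined(createGlycan(monosaccharide("Glc")))  # anomericity unknown
isFullyDefined <- function(g) {
  for (nd in g@nodes) {
    if (is(nd, "Monosaccharide")) {
      if (nd@anomericity == "undetermined" || nd@ring == "undetermined" ||
          nd@config == "undetermined") return(FALSE)
    } else if (is(nd, "RepeatUnit")) {
      if (is.na(nd@minCount) || is.na(nd@maxCount)) return(FALSE)
      il <- nd@internalLinkage
      if (is.na(il@donor) || anyNA(il@acceptors) || length(il@acceptors) > 1L)
        return(FALSE)
      if (!isFullyDefined(nd@internal)) return(FALSE)
    }
  }
  for (e in g@edges) {
    if (is.na(e$linkage@donor) || anyNA(e$linkage@acceptors) ||
        length(e$linkage@acceptors) > 1L) return(FALSE)
  }
  TRUE
}

## ---- canonical ordering shared by the writer and the layout engine ----

## id-independent serialization key of the subtree below (and including) id
.subtreeKey <- function(g, id) {
  nd <- g@nodes[[as.character(id)]]
  own <- if (is(nd, "Monosaccharide"))
    paste("m", nd@mtype, nd@anomericity, nd@ring, nd@config, sep = "~")
  else if (is(nd, "Substituent")) paste("s", nd@stype, sep = "~")
  else paste("r", .fmtPos(nd@minCount), .fmtPos(nd@maxCount),
             .subtreeKey(nd@internal, nd@internal@rootId), sep = "~")
  kids <- .orderChildEdges(g, id)
  if (!length(kids)) return(own)
  paste0(own, "(", paste(vapply(kids, function(e) {
    paste0(.fmtPos(e$linkage@donor), "+",
           paste(.fmtPos(e$linkage@acceptors), collapse = "|"), ":",
           .subtreeKey(g, e$child))
  }, character(1)), collapse = ","), ")")
}

## canonical sibling order: substituents first (by position, then type),
## then glycosidic children by (smallest stated acceptor position with
## UNKNOWN last, then lexicographic subtree key)
.orderChildEdges <- function(g, id) {
  es <- .childEdges(g, id)
  if (length(es) < 2L) return(es)
  isSub <- vapply(es, function(e)
    is(g@nodes[[as.character(e$child)]], "Substituent"), logical(1))
  minAcc <- vapply(es, function(e) {
    a <- e$linkage@acceptors
    if (all(is.na(a))) Inf else min(a, na.rm = TRUE)
  }, numeric(1))
  key <- vapply(es, function(e) .subtreeKey(g, e$child), character(1))
  es[order(!isSub, minAcc, key)]
}
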