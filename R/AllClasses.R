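## S4 classes for the glycan tree model. A Glycan is a rooted directed tree:
## nodes are Monosaccharide, Substituent or RepeatUnit objects addressed by
## stable integer ids; edges carry GlycosidicLinkage payloads. UNKNOWN
## positions are NA_integer_ throughout.

#' @import methods
NULL

#' GlycosidicLinkage: donor/acceptor carbon positions with fuzziness
#'
#' The edge payload of a glycan tree. \code{donor} is the carbon of the child
#' residue forming the bond (its anomeric carbon for glycosidic bonds);
#' \code{acceptors} is a set of candidate attachment positions on the parent.
#' A set of size > 1 encodes alternative attachment points; \code{NA} encodes
#' an UNKNOWN position and never co-occurs with stated alternatives.
#'
#' @slot donor integer(1), 1-9 or NA (UNKNOWN).
#' @slot acceptors integer vector, each 1-9, or a single NA.
#' @export
setClass("GlycosidicLinkage",
         representation(donor = "integer", acceptors = "integer"))

setValidity("GlycosidicLinkage", function(object) {
  a <- object@acceptors
  if (length(object@donor) != 1L) return("donor must be a single position")
  if (length(a) < 1L) return("acceptors must be non-empty")
  if (anyNA(a) && length(a) > 1L)
    return("UNKNOWN acceptor cannot co-occur with stated alternatives")
  ok <- function(p) is.na(p) | (p >= 1L & p <= 9L)
  if (!all(ok(object@donor)) || !all(ok(a)))
    return("positions must be in 1..9 or NA")
  if (!anyNA(a) && anyDuplicated(a)) return("duplicate acceptor positions")
  TRUE
})

#' Construct a glycosidic linkage
#'
#' @param donor Donor-side carbon position (child residue), 1-9 or NA.
#' @param acceptors One or more acceptor positions on the parent; a vector of
#'   length > 1 encodes alternative attachment points, NA encodes UNKNOWN.
#' @return A \linkS4class{GlycosidicLinkage}.
#' @export
#' @examples
#' linkage(1, 4)        # (1->4)
#' linkage(1, c(3, 4))  # fuzzy: attached at 3 or 4
linkage <- function(donor, acceptors) {
  tryCatch(
    new("GlycosidicLinkage",
        donor = as.integer(donor),
        acceptors = sort(as.integer(acceptors), na.last = TRUE)),
    error = function(e) glyStop("glycanRangeError", conditionMessage(e)))
}

#' @rdname GlycanNode-class
#' @export
setClass("GlycanNode", representation("VIRTUAL", nodeId = "integer"))

#' Glycan tree nodes
#'
#' \code{Monosaccharide} carries a vocabulary type token plus anomericity,
#' ring form and absolute configuration (each possibly "undetermined");
#' \code{Substituent} is a childless decoration node; \code{RepeatUnit}
#' wraps an internal glycan repeated \code{minCount}-\code{maxCount} times
#' (NA = UNKNOWN) and behaves as a single node in the host tree.
#'
#' @name GlycanNode-class
#' @aliases Monosaccharide-class Substituent-class RepeatUnit-class
NULL

#' @rdname GlycanNode-class
#' @export
setClass("Monosaccharide", contains = "GlycanNode",
         representation(mtype = "character", anomericity = "character",
                        ring = "character", config = "character"))

setValidity("Monosaccharide", function(object) {
  if (!object@anomericity %in% .anomericities) return("invalid anomericity")
  if (!object@ring %in% .ringForms) return("invalid ring form")
  if (!object@config %in% .absConfigs) return("invalid absolute configuration")
  if (object@ring == "open" && object@anomericity != "open")
    return("open-chain residue must have anomericity 'open'")
  TRUE
})

#' @rdname GlycanNode-class
#' @export
setClass("Substituent", contains = "GlycanNode",
         representation(stype = "character"))

#' Construct a monosaccharide node
#'
#' @param type Monosaccharide type token from \code{monosaccharideTypes()}.
#' @param anomericity One of alpha, beta, open, undetermined.
#' @param ring Ring form; defaults to the type's usual form (pyranose for
#'   most, furanose e.g. for Fru).
#' @param config Absolute configuration; defaults to the type's default
#'   (D for most, L for Fuc, IdoA, Rha, Ara).
#' @return A \linkS4class{Monosaccharide}.
#' @export
#' @examples
#' monosaccharide("Gal", "beta")
#' monosaccharide("Neu", "alpha")
monosaccharide <- function(type, anomericity = "undetermined",
                           ring = NULL, config = NULL) {
  mt <- .getMonoType(type)
  if (is.null(ring))
    ring <- if (mt$default_ring == "f") "furanose" else "pyranose"
  if (is.null(config)) config <- mt$default_config
  tryCatch(
    new("Monosaccharide", nodeId = NA_integer_, mtype = type,
        anomericity = anomericity, ring = ring, config = config),
    error = function(e) glyStop("glycanInvariantError", conditionMessage(e)))
}

#' Construct a substituent node
#'
#' @param type Substituent type token from \code{substituentTypes()}.
#' @return A \linkS4class{Substituent}.
#' @export
substituent <- function(type) {
  .getSubType(type)  # vocabulary check
  new("Substituent", nodeId = NA_integer_, stype = type)
}

#' Glycan: a rooted tree of residues
#'
#' The central container. Nodes are stored in a named list keyed by id;
#' edges are (parent, child, linkage) triples forming a rooted tree whose
#' root is the reducing-end residue. Ids increase monotonically and are
#' never reused after deletion.
#'
#' @slot nodes Named list of \linkS4class{GlycanNode} objects.
#' @slot edges List of \code{list(parent, child, linkage)} triples.
#' @slot rootId Integer id of the reducing-end node (NA when empty).
#' @slot counter Last id handed out (see \code{\link{lastNodeId}}).
#' @export
setClass("Glycan",
         representation(nodes = "list", edges = "list",
                        rootId = "integer", counter = "integer"))

#' @rdname GlycanNode-class
#' @export
setClass("RepeatUnit", contains = "GlycanNode",
         representation(internal = "Glycan",
                        minCount = "integer", maxCount = "integer",
                        internalLinkage = "GlycosidicLinkage",
                        acceptorNodeId = "integer"))

setValidity("RepeatUnit", function(object) {
  if (length(object@internal@nodes) == 0L) return("internal glycan is empty")
  mn <- object@minCount; mx <- object@maxCount
  if (!is.na(mn) && mn < 1L) return("repeat counts must be positive")
  if (!is.na(mx) && mx < 1L) return("repeat counts must be positive")
  if (!is.na(mn) && !is.na(mx) && mn > mx) return("minCount exceeds maxCount")
  TRUE
})

#' Construct a repeating unit
#'
#' @param internal A non-empty \linkS4class{Glycan}: the repeated subtree.
#' @param minCount,maxCount Positive integers or NA (UNKNOWN).
#' @param internalLinkage \linkS4class{GlycosidicLinkage} connecting copy
#'   i's leaf (acceptor side) to copy i+1's root (donor side).
#' @param acceptorNodeId Which internal node receives the next copy; NA
#'   selects the canonically last monosaccharide leaf.
#' @return A \linkS4class{RepeatUnit}.
#' @export
repeatUnit <- function(internal, minCount, maxCount, internalLinkage,
                       acceptorNodeId = NA_integer_) {
  tryCatch(
    new("RepeatUnit", nodeId = NA_integer_, internal = internal,
        minCount = as.integer(minCount), maxCount = as.integer(maxCount),
        internalLinkage = internalLinkage,
        acceptorNodeId = as.integer(acceptorNodeId)),
    error = function(e) glyStop("glycanRangeError", conditionMessage(e)))
}

.glycanValidity <- function(object) {
  ids <- vapply(object@nodes, function(n) n@nodeId, integer(1))
  if (length(ids) && !identical(names(object@nodes), as.character(ids)))
    return("node list names must match node ids")
  if (length(object@nodes) == 0L) {
    if (length(object@edges)) return("empty glycan cannot have edges")
    return(TRUE)
  }
  if (is.na(object@rootId) || !as.character(object@rootId) %in% names(object@nodes))
    return("rootId must name an existing node")
  root <- object@nodes[[as.character(object@rootId)]]
  if (is(root, "Substituent")) return("root must be a monosaccharide or repeat unit")
  if (length(object@edges) != length(object@nodes) - 1L)
    return("edge count must be node count - 1")
  children <- vapply(object@edges, function(e) e$child, integer(1))
  parents  <- vapply(object@edges, function(e) e$parent, integer(1))
  if (anyDuplicated(children)) return("a node has more than one parent")
  if (object@rootId %in% children) return("root cannot be a child")
  if (!all(c(children, parents) %in% ids)) return("edge references unknown node")
  ## reachability from root (cycle/forest guard)
  adj <- split(children, as.character(parents))
  seen <- as.character(object@rootId); queue <- seen
  while (length(queue)) {
    nxt <- unlist(adj[queue], use.names = FALSE)
    queue <- as.character(nxt)
    seen <- c(seen, queue)
  }
  if (length(seen) != length(ids)) return("edges do not form a tree rooted at rootId")
  for (e in object@edges) {
    p <- object@nodes[[as.character(e$parent)]]
    k <- object@nodes[[as.character(e$child)]]
    if (is(p, "Substituent")) return("substituent nodes cannot have children")
    if (is(p, "Monosaccharide")) {
      cc <- .carbonCount(p@mtype)
      a <- e$linkage@acceptors
      if (any(!is.na(a) & a > cc))
        return(sprintf("acceptor position beyond carbon count of node %d", e$parent))
    }
    if (is(k, "Monosaccharide")) {
      d <- e$linkage@donor
      if (!is.na(d) && d > .getMonoType(k@mtype)$carbon_count)
        return(sprintf("donor position beyond carbon count of node %d", e$child))
    }
  }
  ## no two monosaccharide/repeat children of one parent on the same
  ## fully-stated acceptor position
  for (pid in unique(parents)) {
    es <- object@edges[parents == pid]
    glyc <- Filter(function(e) !is(object@nodes[[as.character(e$child)]], "Substituent"), es)
    pos <- unlist(lapply(glyc, function(e) {
      a <- e$linkage@acceptors
      if (length(a) == 1L && !is.na(a)) a else integer(0)
    }))
    if (anyDuplicated(pos))
      return(sprintf("attachment conflict at node %d", pid))
  }
  TRUE
}

setValidity("Glycan", .glycanValidity)

#' @describeIn Glycan Display a compact summary of the tree.
#' @param object A Glycan.
#' @export
setMethod("show", "Glycan", function(object) {
  n <- length(object@nodes)
  if (n == 0L) { cat("Glycan (empty)\n"); return(invisible(NULL)) }
  cat(sprintf("Glycan with %d node%s (%s)\n", n, if (n == 1) "" else "s",
              if (isFullyDefined(object)) "fully defined" else "fuzzy"))
  describe <- function(id, depth) {
    nd <- object@nodes[[as.character(id)]]
    lab <- if (is(nd, "Monosaccharide"))
      sprintf("%s (%s, %s, %s)", nd@mtype, nd@anomericity, nd@ring, nd@config)
    else if (is(nd, "Substituent")) sprintf("substituent %s", nd@stype)
    else sprintf("repeat x%s-%s [%d nodes]",
                 ifelse(is.na(nd@minCount), "?", nd@minCount),
                 ifelse(is.na(nd@maxCount), "?", nd@maxCount),
                 length(nd@internal@nodes))
    cat(strrep("  ", depth), "- [", id, "] ", lab, "\n", sep = "")
    for (e in object@edges) if (e$parent == id) {
      a <- e$linkage@acceptors
      cat(strrep("  ", depth + 1), "(",
          .fmtPos(e$linkage@donor), "->",
          paste(.fmtPos(a), collapse = "|"), ")\n", sep = "")
      describe(e$child, depth + 1)
    }
  }
  describe(object@rootId, 0)
  invisible(NULL)
})

setMethod("show", "Monosaccharide", function(object) {
  cat(sprintf("Monosaccharide %s (%s, %s, %s)\n", object@mtype,
              object@anomericity, object@ring, object@config))
})

setMethod("show", "GlycosidicLinkage", function(object) {
  cat(sprintf("Linkage (%s->%s)\n", .fmtPos(object@donor),
              paste(.fmtPos(object@acceptors), collapse = "|")))
})
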