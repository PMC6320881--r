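## Grid layout. The reducing end sits at cell (0, 0) and the structure grows
## leftward: every child column is parent column - 1, so columns encode
## distance from the reducing end. The preferred row offset encodes the
## acceptor position of the linkage (the bond-angle convention: a 6-linked
## branch rises, a 3-linked branch drops, 2-/4-linked children run level),
## and an occupancy grid resolves residual collisions deterministically.

#' GridLayout: injective node-to-cell assignment
#'
#' @slot cells data.frame with columns \code{nodeId}, \code{col}, \code{row};
#'   one row per visible node (substituents fuse into their parent's cell
#'   and get no cell of their own).
#' @export
setClass("GridLayout", representation(cells = "data.frame"))

setValidity("GridLayout", function(object) {
  d <- object@cells
  if (!all(c("nodeId", "col", "row") %in% names(d)))
    return("cells needs nodeId/col/row columns")
  if (anyDuplicated(paste(d$col, d$row))) return("duplicate grid cells")
  TRUE
})

#' @rdname GridLayout-class
#' @param object A GridLayout.
#' @export
setMethod("show", "GridLayout", function(object) {
  cat(sprintf("GridLayout with %d cells\n", nrow(object@cells)))
  if (nrow(object@cells)) print(utils::head(object@cells, 10))
})

#' @rdname layoutGlycan
#' @export
layoutCells <- function(layout) layout@cells

## preferred row offset by smallest stated acceptor position
.angleOffset <- function(acceptors) {
  if (all(is.na(acceptors))) return(0L)
  p <- min(acceptors, na.rm = TRUE)
  if (p == 6L) 1L else if (p == 3L) -1L else 0L
}

#' Deterministic collision resolution on the grid
#'
#' Returns \code{desired} if that cell is free, otherwise the nearest free
#' row in the same column probing offsets +1, -1, +2, -2, ...
#'
#' @param occupied A two-column matrix or data.frame of occupied (col, row)
#'   cells (may have zero rows).
#' @param desired Length-2 integer vector (col, row).
#' @return Length-2 integer vector: the assigned free cell.
#' @export
#' @examples
#' resolveCollision(cbind(col = -1, row = 0), c(-1, 0))  # probes row +1
resolveCollision <- function(occupied, desired) {
  occ <- if (is.null(occupied) || NROW(occupied) == 0L) character(0)
         else paste(occupied[, 1], occupied[, 2])
  col <- desired[1]; row <- desired[2]
  if (!(paste(col, row) %in% occ)) return(c(col, row))
  k <- 1L
  repeat {
    for (dr in c(k, -k)) {
      cand <- row + dr
      if (!(paste(col, cand) %in% occ)) return(c(col, cand))
    }
    k <- k + 1L
  }
}

#' Lay a glycan out on the integer grid
#'
#' Assigns each monosaccharide and repeat-unit node a unique (col, row)
#' cell: the root at (0, 0), children one column to the left of their
#' parent, rows chosen by the linkage-angle convention with deterministic
#' collision avoidance. Substituents take no cell (they are drawn fused
#' into their parent symbol). For multi-alternative acceptor sets the
#' smallest stated position drives the geometry.
#'
#' @param g A non-empty \linkS4class{Glycan}.
#' @return A \linkS4class{GridLayout}.
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("Glc", "beta"))
#' g <- addMonosaccharide(g, 1, monosaccharide("Gal", "beta"), linkage(1, 4))
#' layoutCells(layoutGlycan(g))
layoutGlycan <- function(g) {
  if (glycanSize(g) == 0L)
    return(new("GridLayout",
               cells = data.frame(nodeId = integer(0), col = integer(0),
                                  row = integer(0))))
  ids <- integer(0); cols <- integer(0); rows <- integer(0)
  place <- function(id, col, row) {
    ids <<- c(ids, id); cols <<- c(cols, col); rows <<- c(rows, row)
  }
  place(g@rootId, 0L, 0L)
  walk <- function(id, col, row) {
    for (e in .orderChildEdges(g, id)) {
      if (is(g@nodes[[as.character(e$child)]], "Substituent")) next
      desired <- c(col - 1L, row + .angleOffset(e$linkage@acceptors))
      cell <- resolveCollision(cbind(cols, rows), desired)
      place(e$child, cell[1], cell[2])
      walk(e$child, cell[1], cell[2])
    }
  }
  walk(g@rootId, 0L, 0L)
  new("GridLayout",
      cells = data.frame(nodeId = ids, col = cols, row = rows))
}
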