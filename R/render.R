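## SNFG SVG renderer. Symbols are drawn from the shape/colour vocabulary;
## composite residues (amino sugar + N-acyl) fuse to their single SNFG
## symbol; other substituents become short text decorations ("6S"). Edge
## anomericity is dash-coded: beta solid, alpha dashed, undetermined dotted.
## Output is deterministic: identical input gives byte-identical SVG.

#' Rendering options
#'
#' @slot cellPx Pixels per grid cell.
#' @slot symbolPx Symbol diameter in pixels (must be < cellPx).
#' @slot showLinkageLabels Draw "d->a" labels at edge midpoints?
#' @slot dashAlpha,dashUndetermined SVG stroke-dasharray patterns.
#' @export
setClass("RenderOptions",
         representation(cellPx = "numeric", symbolPx = "numeric",
                        showLinkageLabels = "logical",
                        dashAlpha = "character",
                        dashUndetermined = "character"))

setValidity("RenderOptions", function(object) {
  if (object@symbolPx >= object@cellPx)
    return("symbolPx must be smaller than cellPx")
  TRUE
})

#' @rdname RenderOptions-class
#' @param cellPx,symbolPx,showLinkageLabels,dashAlpha,dashUndetermined See slots.
#' @export
renderOptions <- function(cellPx = 60, symbolPx = 30,
                          showLinkageLabels = TRUE,
                          dashAlpha = "6,4", dashUndetermined = "2,3") {
  o <- new("RenderOptions", cellPx = cellPx, symbolPx = symbolPx,
           showLinkageLabels = showLinkageLabels,
           dashAlpha = dashAlpha, dashUndetermined = dashUndetermined)
  validObject(o)
  o
}

#' Dash pattern for an anomericity
#'
#' Total over the anomericity vocabulary: beta and open-chain edges are
#' solid (empty pattern), alpha edges dashed, undetermined edges dotted.
#'
#' @param anomericity One of alpha, beta, open, undetermined.
#' @param options A \linkS4class{RenderOptions}.
#' @return The stroke-dasharray token ("" = solid).
#' @export
#' @examples
#' edgeStyle("alpha")
#' edgeStyle("beta")
edgeStyle <- function(anomericity, options = renderOptions()) {
  switch(anomericity,
         alpha = options@dashAlpha,
         beta = "",
         open = "",
         undetermined = options@dashUndetermined,
         glyStop("glycanVocabularyError",
                 sprintf("unknown anomericity '%s'", anomericity)))
}

#' SNFG symbol for a residue with its attached substituents
#'
#' Applies the fusion table (e.g. GlcN + n-acetyl@2 becomes the blue GlcNAc
#' square; Neu + n-acetyl@5 the purple Neu5Ac diamond); substituents that do
#' not fuse are returned as text decorations such as \code{"6S"}.
#'
#' @param type Monosaccharide type token.
#' @param subs Optional data.frame with columns \code{name} and
#'   \code{position} describing attached substituents.
#' @return A list with \code{shape}, \code{color}, \code{hex},
#'   \code{label} (fused display name or the type token) and
#'   \code{decorations} (character vector).
#' @export
#' @examples
#' symbolFor("LDmanHep")                                   # green hexagon
#' symbolFor("GlcN", data.frame(name = "n-acetyl", position = 2))
symbolFor <- function(type, subs = NULL) {
  mt <- .getMonoType(type)
  shape <- mt$snfg_shape; color <- mt$snfg_color; label <- mt$name
  decorations <- character(0)
  if (!is.null(subs) && nrow(subs)) {
    fus <- .vocabGet("fusions")
    used <- rep(FALSE, nrow(subs))
    for (i in seq_len(nrow(fus))) {
      if (fus$base[i] != type) next
      hit <- which(!used & subs$name == fus$substituent[i] &
                   !is.na(subs$position) & subs$position == fus$position[i])
      if (length(hit)) {
        shape <- fus$snfg_shape[i]; color <- fus$snfg_color[i]
        label <- fus$display_name[i]
        used[hit[1]] <- TRUE
        break
      }
    }
    for (i in which(!used)) {
      st <- .getSubType(subs$name[i])
      decorations <- c(decorations,
                       paste0(ifelse(is.na(subs$position[i]), "?",
                                     subs$position[i]), st$label))
    }
  }
  list(shape = shape, color = color, hex = unname(snfgPalette()[color]),
       label = label, decorations = decorations)
}

.fmt <- function(x) sprintf("%.2f", x)

.polygon <- function(pts, fill) {
  sprintf('<polygon points="%s" fill="%s" stroke="#000000" stroke-width="1.5"/>',
          paste(vapply(pts, function(p) paste0(.fmt(p[1]), ",", .fmt(p[2])),
                       character(1)), collapse = " "), fill)
}

.regularPoints <- function(x, y, r, n, startDeg = -90) {
  a <- (startDeg + (0:(n - 1)) * 360 / n) * pi / 180
  lapply(seq_len(n), function(i) c(x + r * cos(a[i]), y + r * sin(a[i])))
}

.symbolElements <- function(shape, hex, x, y, s) {
  h <- s / 2
  white <- "#FFFFFF"
  rect <- function(fill)
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#000000" stroke-width="1.5"/>',
            .fmt(x - h), .fmt(y - h), .fmt(s), .fmt(s), fill)
  switch(shape,
    circle = sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#000000" stroke-width="1.5"/>',
                     .fmt(x), .fmt(y), .fmt(h), hex),
    square = rect(hex),
    `crossed-square` = paste0(
      rect(white),
      .polygon(list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h)), hex),
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1.5"/>',
              .fmt(x - h), .fmt(y - h), .fmt(x + h), .fmt(y + h))),
    `divided-diamond` = paste0(
      .polygon(list(c(x, y - h), c(x + h, y), c(x, y + h), c(x - h, y)), white),
      .polygon(list(c(x - h, y), c(x, y - h), c(x + h, y)), hex)),
    triangle = .polygon(list(c(x - h, y + h), c(x + h, y + h), c(x, y - h)), hex),
    `divided-triangle` = paste0(
      .polygon(list(c(x - h, y + h), c(x + h, y + h), c(x, y - h)), white),
      .polygon(list(c(x - h, y + h), c(x, y + h), c(x, y - h)), hex)),
    rectangle = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#000000" stroke-width="1.5"/>',
                        .fmt(x - h), .fmt(y - h / 2), .fmt(s), .fmt(h), hex),
    `flat-rectangle` = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#000000" stroke-width="1.5"/>',
                               .fmt(x - h), .fmt(y - s / 6), .fmt(s), .fmt(s / 3), hex),
    star = {
      outer <- .regularPoints(x, y, h, 5)
      inner <- .regularPoints(x, y, 0.4 * h, 5, startDeg = -90 + 36)
      pts <- list()
      for (i in 1:5) { pts <- c(pts, outer[i], inner[i]) }
      .polygon(pts, hex)
    },
    diamond = .polygon(list(c(x, y - h), c(x + h, y), c(x, y + h), c(x - h, y)), hex),
    hexagon = .polygon(list(c(x - h, y), c(x - h / 2, y - 0.3 * s),
                            c(x + h / 2, y - 0.3 * s), c(x + h, y),
                            c(x + h / 2, y + 0.3 * s), c(x - h / 2, y + 0.3 * s)),
                       hex),
    pentagon = .polygon(.regularPoints(x, y, h, 5), hex),
    glyStop("glycanVocabularyError", sprintf("unknown SNFG shape '%s'", shape))
  )
}

#' Render a glycan to SNFG-compliant SVG
#'
#' One symbol group per monosaccharide/repeat node, one line per glycosidic
#' edge with the anomericity dash code, optional "donor->acceptor" linkage
#' labels at edge midpoints, repeat units bracketed with their min-max
#' annotation. SVG y grows downward, so the +1 row (a 6-linked branch)
#' appears above its parent.
#'
#' @param g A \linkS4class{Glycan}.
#' @param layout A \linkS4class{GridLayout}; computed if missing.
#' @param options A \linkS4class{RenderOptions}.
#' @return SVG 1.1 document text.
#' @export
#' @examples
#' g <- createGlycan(monosaccharide("Glc", "beta"))
#' svg <- renderSVG(g)
renderSVG <- function(g, layout = layoutGlycan(g), options = renderOptions()) {
  header <- '<?xml version="1.0" encoding="UTF-8"?>\n'
  if (glycanSize(g) == 0L)
    return(paste0(header,
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="10" height="10"/>\n'))
  cells <- layout@cells
  cp <- options@cellPx; sp <- options@symbolPx
  minCol <- min(cells$col); maxCol <- max(cells$col)
  minRow <- min(cells$row); maxRow <- max(cells$row)
  px <- function(col) (col - minCol + 1) * cp
  py <- function(row) (maxRow - row + 1) * cp
  width <- (maxCol - minCol + 2) * cp
  height <- (maxRow - minRow + 2) * cp
  pos <- function(id) {
    i <- match(id, cells$nodeId)
    c(px(cells$col[i]), py(cells$row[i]))
  }

  edgeElems <- character(0)
  for (e in g@edges) {
    kid <- g@nodes[[as.character(e$child)]]
    if (is(kid, "Substituent")) next
    if (!(e$parent %in% cells$nodeId) || !(e$child %in% cells$nodeId)) next
    p1 <- pos(e$parent); p2 <- pos(e$child)
    anom <- if (is(kid, "Monosaccharide")) kid@anomericity
            else {
              r <- kid@internal@nodes[[as.character(kid@internal@rootId)]]
              if (is(r, "Monosaccharide")) r@anomericity else "undetermined"
            }
    dash <- edgeStyle(anom, options)
    dashAttr <- if (nzchar(dash)) sprintf(' stroke-dasharray="%s"', dash) else ""
    edgeElems <- c(edgeElems,
      sprintf('<line class="edge" data-anomericity="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="2"%s/>',
              anom, .fmt(p1[1]), .fmt(p1[2]), .fmt(p2[1]), .fmt(p2[2]), dashAttr))
    if (options@showLinkageLabels) {
      a <- e$linkage@acceptors
      lab <- paste0(.labPos(e$linkage@donor), "→",
                    if (all(is.na(a))) "?" else paste(a, collapse = "/"))
      edgeElems <- c(edgeElems,
        sprintf('<text class="linkage-label" x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif">%s</text>',
                .fmt((p1[1] + p2[1]) / 2), .fmt((p1[2] + p2[2]) / 2 - 3),
                .fmt(sp * 0.4), lab))
    }
  }

  nodeElems <- character(0)
  for (i in seq_len(nrow(cells))) {
    id <- cells$nodeId[i]
    nd <- g@nodes[[as.character(id)]]
    x <- px(cells$col[i]); y <- py(cells$row[i])
    if (is(nd, "RepeatUnit")) {
      mn <- if (is.na(nd@minCount)) "?" else nd@minCount
      mx <- if (is.na(nd@maxCount)) "?" else nd@maxCount
      h <- sp / 2
      inner <- nd@internal@nodes[[as.character(nd@internal@rootId)]]
      innerSym <- if (is(inner, "Monosaccharide")) {
        sf <- symbolFor(inner@mtype)
        .symbolElements(sf$shape, sf$hex, x, y, sp * 0.8)
      } else ""
      nodeElems <- c(nodeElems, sprintf(
        '<g class="residue repeat" data-node="%d">%s<path d="M %s %s L %s %s L %s %s L %s %s" fill="none" stroke="#000000" stroke-width="1.5"/><path d="M %s %s L %s %s L %s %s L %s %s" fill="none" stroke="#000000" stroke-width="1.5"/><text x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif">%s</text></g>',
        id, innerSym,
        .fmt(x - h), .fmt(y - h), .fmt(x - h - 6), .fmt(y - h),
        .fmt(x - h - 6), .fmt(y + h), .fmt(x - h), .fmt(y + h),
        .fmt(x + h), .fmt(y - h), .fmt(x + h + 6), .fmt(y - h),
        .fmt(x + h + 6), .fmt(y + h), .fmt(x + h), .fmt(y + h),
        .fmt(x + h + 8), .fmt(y + h + 10), .fmt(sp * 0.4),
        paste0(mn, "–", mx)))
      next
    }
    subs <- do.call(rbind, lapply(.childEdges(g, id), function(e2) {
      kid <- g@nodes[[as.character(e2$child)]]
      if (!is(kid, "Substituent")) return(NULL)
      a <- e2$linkage@acceptors
      data.frame(name = kid@stype,
                 position = if (length(a) == 1L) a else NA_integer_)
    }))
    sf <- symbolFor(nd@mtype, subs)
    deco <- if (length(sf$decorations))
      sprintf('<text class="decoration" x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif">%s</text>',
              .fmt(x), .fmt(y + sp * 0.5 + 11), .fmt(sp * 0.4),
              paste(sf$decorations, collapse = " "))
    else ""
    nodeElems <- c(nodeElems,
      sprintf('<g class="residue" data-node="%d" data-shape="%s" data-color="%s">%s%s</g>',
              id, sf$shape, sf$color,
              .symbolElements(sf$shape, sf$hex, x, y, sp), deco))
  }

  paste0(header,
         sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s">\n',
                 .fmt(width), .fmt(height)),
         paste(c(edgeElems, nodeElems), collapse = "\n"),
         "\n</svg>\n")
}

.labPos <- function(p) ifelse(is.na(p), "?", as.character(p))
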