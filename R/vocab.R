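## Controlled vocabularies: monosaccharide types, substituent types, the SNFG
## palette and the base+substituent symbol-fusion table. Loaded once from the
## plain-text tables under inst/extdata and cached in a package environment.

.vocab <- new.env(parent = emptyenv())

.anomericities <- c("alpha", "beta", "open", "undetermined")
.ringForms     <- c("pyranose", "furanose", "open", "undetermined")
.absConfigs    <- c("D", "L", "undetermined")
.superclassCarbons <- c(TRI = 3L, TET = 4L, PEN = 5L, HEX = 6L,
                        HEP = 7L, OCT = 8L, NON = 9L)

.readVocabTable <- function(file) {
  path <- system.file("extdata", file, package = "glycanKit")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install use
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "-")
}

## Free-monosaccharide composition from superclass and chain modifications.
## Base C_n H_2n O_n; deoxy removes O, acid oxidizes CH2OH/CHO to COOH,
## an amine swaps one hydroxyl for NH2.
.typeFormula <- function(n, mods, hasAmine) {
  f <- c(C = n, H = 2L * n, N = 0L, O = n, S = 0L, P = 0L)
  for (m in mods) {
    kind <- sub("^[0-9]+:", "", m)
    if (kind == "d") f["O"] <- f["O"] - 1L
    else if (kind == "a") { f["O"] <- f["O"] + 1L; f["H"] <- f["H"] - 2L }
    else if (kind == "en") f["H"] <- f["H"] - 2L
    ## keto: no compositional change
  }
  if (hasAmine) { f["N"] <- f["N"] + 1L; f["H"] <- f["H"] + 1L; f["O"] <- f["O"] - 1L }
  f
}

.parseMods <- function(s) {
  if (is.na(s) || s == "") return(character(0))
  strsplit(s, ",", fixed = TRUE)[[1]]
}

.loadVocabularies <- function() {
  mono <- .readVocabTable("monosaccharide_types.tsv")
  subs <- .readVocabTable("substituent_types.tsv")
  cols <- .readVocabTable("snfg_colors.tsv")
  fus  <- .readVocabTable("symbol_fusions.tsv")

  stopifnot(all(mono$superclass %in% names(.superclassCarbons)),
            all(mono$carbon_count == .superclassCarbons[mono$superclass]),
            all(mono$anomeric_carbon %in% 1:2),
            !anyDuplicated(paste(mono$snfg_shape, mono$snfg_color)),
            all(mono$snfg_color %in% cols$name))

  mono$carbon_count <- as.integer(mono$carbon_count)
  mono$anomeric_carbon <- as.integer(mono$anomeric_carbon)
  mono$amine_position <- suppressWarnings(as.integer(mono$amine_position))

  formulas <- lapply(seq_len(nrow(mono)), function(i) {
    .typeFormula(mono$carbon_count[i], .parseMods(mono$mods[i]),
                 !is.na(mono$amine_position[i]))
  })
  names(formulas) <- mono$name

  ## Descriptor lookup: stereo with the configuration letter of the final
  ## segment removed, keyed together with superclass and sorted modifications.
  ## Amino-sugar types are reached through post-hoc fusion, not this map.
  descKey <- function(stereo, superclass, mods) {
    segs <- strsplit(stereo, "-", fixed = TRUE)[[1]]
    last <- segs[length(segs)]
    segs[length(segs)] <- substring(last, 2)
    paste(paste(segs, collapse = "-"), superclass,
          paste(sort(.parseMods(mods)), collapse = ","), sep = "/")
  }
  base <- mono[is.na(mono$amine_position), ]
  lookup <- structure(base$name,
                      names = vapply(seq_len(nrow(base)), function(i)
                        descKey(base$stereo[i], base$superclass[i], base$mods[i]),
                        character(1)))
  stopifnot(!anyDuplicated(names(lookup)))

  ## base name -> amine-variant name at a given position (e.g. Glc@2 -> GlcN)
  am <- mono[!is.na(mono$amine_position), ]
  amineMap <- list()
  for (i in seq_len(nrow(am))) {
    k <- descKey(am$stereo[i], am$superclass[i], am$mods[i])
    b <- unname(lookup[k])
    amineMap[[paste(b, am$amine_position[i], sep = "@")]] <- am$name[i]
  }

  deltas <- lapply(seq_len(nrow(subs)), function(i) {
    list(hydroxyl = c(C = subs$dC[i], H = subs$dH[i], N = subs$dN[i],
                      O = subs$dO[i], S = subs$dS[i], P = subs$dP[i]),
         amine = if (!is.na(subs$aC[i]))
           c(C = subs$aC[i], H = subs$aH[i], N = subs$aN[i],
             O = subs$aO[i], S = 0, P = 0))
  })
  names(deltas) <- subs$name

  assign("carbonCounts", structure(mono$carbon_count, names = mono$name),
         envir = .vocab)
  assign("anomericCarbons", structure(mono$anomeric_carbon, names = mono$name),
         envir = .vocab)
  assign("aminePositions", structure(mono$amine_position, names = mono$name),
         envir = .vocab)
  assign("monoModsList",
         structure(lapply(mono$mods, .parseMods), names = mono$name),
         envir = .vocab)
  assign("mono", mono, envir = .vocab)
  assign("monoFormulas", formulas, envir = .vocab)
  assign("descLookup", lookup, envir = .vocab)
  assign("descKeyFun", descKey, envir = .vocab)
  assign("amineMap", amineMap, envir = .vocab)
  assign("subs", subs, envir = .vocab)
  assign("subDeltas", deltas, envir = .vocab)
  assign("colors", structure(cols$hex, names = cols$name), envir = .vocab)
  assign("fusions", fus, envir = .vocab)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) .loadVocabularies()

.vocabGet <- function(what) {
  if (!exists(what, envir = .vocab)) .loadVocabularies()
  get(what, envir = .vocab)
}

#' Monosaccharide vocabulary
#'
#' The controlled vocabulary of monosaccharide types shipped with the package.
#' Each row maps a short token (e.g. \code{Gal}, \code{GlcN}, \code{Neu},
#' \code{LDmanHep}) to its superclass, carbon count, anomeric carbon, SNFG
#' shape and colour, default absolute configuration and ring form, GlycoCT
#' stereo descriptor, chain modifications and (for amino sugars) the amine
#' position.
#'
#' @return A data.frame, one row per monosaccharide type.
#' @export
#' @examples
#' head(monosaccharideTypes())
monosaccharideTypes <- function() .vocabGet("mono")

#' Substituent vocabulary
#'
#' Non-sugar decorations (N-acetyl, sulfate, phosphate, methyl, ...) with
#' their display labels, attachment mode (\code{d} replaces the hydroxyl,
#' \code{o} replaces the hydroxyl hydrogen) and compositional deltas.
#'
#' @return A data.frame, one row per substituent type.
#' @export
substituentTypes <- function() .vocabGet("subs")

#' SNFG colour palette
#'
#' The ten-colour SNFG palette as a named vector of hex values.
#'
#' @return Named character vector mapping colour tokens to hex codes.
#' @export
snfgPalette <- function() .vocabGet("colors")

.getMonoType <- function(name) {
  mono <- .vocabGet("mono")
  i <- match(name, mono$name)
  if (is.na(i))
    glyStop("glycanVocabularyError",
            sprintf("unknown monosaccharide type '%s'", name))
  as.list(mono[i, ])
}

.getSubType <- function(name) {
  subs <- .vocabGet("subs")
  i <- match(name, subs$name)
  if (is.na(i))
    glyStop("glycanVocabularyError",
            sprintf("unknown substituent type '%s'", name))
  as.list(subs[i, ])
}

.monoFormula <- function(name) .vocabGet("monoFormulas")[[name]]

.carbonCount <- function(name) {
  cc <- .vocabGet("carbonCounts")[name]
  if (anyNA(cc))
    glyStop("glycanVocabularyError",
            sprintf("unknown monosaccharide type '%s'", name))
  unname(cc)
}
.anomericCarbon <- function(name) unname(.vocabGet("anomericCarbons")[name])
.aminePosition <- function(name) unname(.vocabGet("aminePositions")[name])
.monoMods <- function(name) .vocabGet("monoModsList")[[name]]
.subDelta <- function(name, context = c("hydroxyl", "amine")) {
  context <- match.arg(context)
  d <- .vocabGet("subDeltas")[[name]][[context]]
  if (is.null(d))
    glyStop("glycanVocabularyError",
            sprintf("substituent '%s' has no %s-attachment form", name, context))
  d
}
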