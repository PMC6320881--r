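## Shared internal helpers.

## Signal a classed error so callers (and the CLI) can dispatch on condition
## class rather than matching message text.
glyStop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "glycanError", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

.fmtPos <- function(p) ifelse(is.na(p), "-1", as.character(p))

## element order for Hill formula strings (C, H first, then alphabetical)
.hillOrder <- c("C", "H", "N", "O", "P", "S")

#' Format an element-count vector as a Hill-order formula string
#'
#' @param counts Named numeric vector of element counts (C, H, N, O, S, P).
#' @return A single string such as \code{"C12H22O11"}.
#' @export
formulaString <- function(counts) {
  counts <- counts[.hillOrder[.hillOrder %in% names(counts)]]
  counts <- counts[counts != 0]
  paste0(vapply(names(counts), function(e) {
    n <- counts[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}

.zeroFormula <- function() c(C = 0, H = 0, N = 0, O = 0, S = 0, P = 0)

.addFormula <- function(a, b) {
  out <- .zeroFormula()
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}
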