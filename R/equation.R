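# Reaction-equation grammar:
#   side  := term ('+' term)*   (either side may be empty: exchange reactions)
#   term  := [coefficient] species
#   coefficient := decimal number or integer fraction 'a/b', whitespace-separated
#   species     := identifier, optionally tagged '[compartment]'
#   arrows: '->' '=>' (irreversible)  '<=>' '<->' (reversible); unicode variants

.ARROWS <- list(
  reversible = c("<=>", "<->", "⇌", "↔"),
  irreversible = c("->", "=>", "→")
)

#' Parse a reaction equation string
#'
#' @param text equation such as `"glc[c] + 2 atp[c] -> g6p[c] + 2 adp[c]"`.
#'   Coefficients default to 1 and may be decimals or integer fractions
#'   (`"3/2"`). `<=>` (or `<->`) marks a reversible reaction, `->` an
#'   irreversible one. An empty side denotes an exchange with the outside,
#'   e.g. `"-> co2[e]"` (uptake positive).
#' @return list with `stoichiometry` (named numeric; negative = consumed)
#'   and `reversible` (logical). Species appearing on both sides are summed
#'   to their net coefficient; exact zeros are dropped.
#' @examples
#' parseReactionEquation("glc[c] + 2 atp[c] -> g6p[c] + 2 adp[c]")
#' parseReactionEquation("dhap[h] <=> dhap[c]")
#' @export
parseReactionEquation <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("equation text must be a single non-empty string")
  }
  arrow <- NULL; arrowPos <- NULL; reversible <- NA
  for (a in .ARROWS$reversible) {
    p <- regexpr(a, text, fixed = TRUE)
    if (p > 0) { arrow <- a; arrowPos <- p; reversible <- TRUE; break }
  }
  if (is.null(arrow)) {
    for (a in .ARROWS$irreversible) {
      p <- regexpr(a, text, fixed = TRUE)
      if (p > 0) { arrow <- a; arrowPos <- p; reversible <- FALSE; break }
    }
  }
  if (is.null(arrow)) {
    stop(sprintf("parse error at position 1: no reaction arrow ('->' or '<=>') in \"%s\"", text))
  }
  lhs <- substr(text, 1L, arrowPos - 1L)
  rhs <- substr(text, arrowPos + nchar(arrow), nchar(text))
  co <- c(.parseSide(lhs, -1, 0L, text),
          .parseSide(rhs, +1, arrowPos + nchar(arrow) - 1L, text))
  if (length(co)) {
    agg <- tapply(co, names(co), sum)
    co <- stats::setNames(as.numeric(agg), names(agg))[unique(names(co))]
    co <- co[co != 0]
  }
  list(stoichiometry = co, reversible = reversible)
}

# sign: -1 substrates, +1 products; offset: char offset of this side in text
.parseSide <- function(side, sign, offset, text) {
  if (!nzchar(trimws(side))) return(stats::setNames(numeric(0), character(0)))
  pieces <- strsplit(side, "+", fixed = TRUE)[[1]]
  pos <- offset + 1L
  out <- numeric(0)
  for (piece in pieces) {
    term <- trimws(piece)
    if (!nzchar(term)) {
      stop(sprintf("parse error at position %d: empty term in \"%s\"", pos, text))
    }
    toks <- strsplit(term, "\\s+")[[1]]
    coef <- 1
    if (length(toks) > 1L && grepl("^[0-9.][0-9.eE/+-]*$", toks[1])) {
      coef <- .parseCoefficient(toks[1], pos, text)
      toks <- toks[-1L]
    }
    species <- paste(toks, collapse = " ")
    out <- c(out, stats::setNames(sign * coef, species))
    pos <- pos + nchar(piece) + 1L
  }
  out
}

.parseCoefficient <- function(tok, pos, text) {
  if (grepl("^[0-9]+/[0-9]+$", tok)) {
    ab <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]])
    if (ab[2] == 0) {
      stop(sprintf("parse error at position %d: zero denominator in \"%s\"", pos, text))
    }
    return(ab[1] / ab[2])
  }
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) {
    stop(sprintf("parse error at position %d: non-numeric coefficient '%s' in \"%s\"",
                 pos, tok, text))
  }
  v
}

#' Format a stoichiometry as a canonical equation string
#'
#' Inverse of [parseReactionEquation()] on canonical forms: coefficients of
#' one are omitted, species keep their order of appearance, sides are joined
#' with `" + "` and the arrow is `"->"` or `"<=>"`.
#'
#' @param stoichiometry named numeric vector of signed coefficients
#' @param reversible logical
#' @return equation string
#' @export
formatReactionEquation <- function(stoichiometry, reversible = FALSE) {
  fmtTerm <- function(id, coef) {
    if (coef == 1) id else paste(format(coef, digits = 15), id)
  }
  lhs <- names(stoichiometry)[stoichiometry < 0]
  rhs <- names(stoichiometry)[stoichiometry > 0]
  l <- paste(mapply(fmtTerm, lhs, -stoichiometry[lhs]), collapse = " + ")
  r <- paste(mapply(fmtTerm, rhs, stoichiometry[rhs]), collapse = " + ")
  trimws(paste(l, if (reversible) "<=>" else "->", r))
}
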