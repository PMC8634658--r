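# Standard atomic weights (IUPAC 2021, abridged to six significant figures)
# for the elements that occur in metabolic reconstructions.
ATOMIC_MASSES <- c(
  H = 1.00800, He = 4.00260, Li = 6.94000, Be = 9.01218, B = 10.8100,
  C = 12.0110, N = 14.0070, O = 15.9990, F = 18.9984, Ne = 20.1797,
  Na = 22.9898, Mg = 24.3050, Al = 26.9815, Si = 28.0850, P = 30.9738,
  S = 32.0600, Cl = 35.4500, K = 39.0980, Ar = 39.9500, Ca = 40.0780,
  Cr = 51.9961, Mn = 54.9380, Fe = 55.8450, Co = 58.9332, Ni = 58.6934,
  Cu = 63.5460, Zn = 65.3800, As = 74.9216, Se = 78.9710, Br = 79.9040,
  Mo = 95.9500, Ag = 107.868, Cd = 112.414, Sn = 118.710, I = 126.904,
  Ba = 137.327, W = 183.840, Hg = 200.592, Pb = 207.200
)

# Pseudo-elements used by reconstruction databases for generic moieties
# (acyl chains, undefined R-groups). Formulas containing them cannot be
# mass-balanced or weighed.
PSEUDO_ELEMENTS <- c("R", "X")

#' Parse a chemical formula into an element tally
#'
#' Parses element-count strings of the form `([A-Z][a-z]?count?)*`, e.g.
#' `"C6H12O6"` or `"C10H12N5O7PR"`. Counts may be absent (meaning 1) and may
#' be fractional, as encountered in lumped biomass-style species. The
#' pseudo-elements `R` and `X` denote generic moieties; a tally containing
#' them is flagged non-balanceable and refuses a molecular weight.
#'
#' @param text a single formula string.
#' @return an `element_tally`: named numeric vector of counts with a logical
#'   attribute `balanceable`.
#' @examples
#' parse_formula("C6H12O6")
#' attr(parse_formula("C10H12N5O7PR"), "balanceable")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (is.na(text) || text == "") {
    return(structure(stats::setNames(numeric(0), character(0)),
                     class = "element_tally", balanceable = TRUE))
  }
  pat <- "([A-Z][a-z]?)([0-9]+(?:\\.[0-9]+)?)?"
  matches <- gregexpr(pat, text, perl = TRUE)[[1]]
  covered <- sum(attr(matches, "match.length"))
  if (matches[1] == -1L || covered != nchar(text)) {
    stop("malformed chemical formula: '", text, "'", call. = FALSE)
  }
  parts <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  syms <- sub(pat, "\\1", parts, perl = TRUE)
  cnts <- sub(pat, "\\2", parts, perl = TRUE)
  cnts <- as.numeric(ifelse(cnts == "", "1", cnts))
  tally <- tapply(cnts, syms, sum)
  tally <- stats::setNames(as.numeric(tally), names(tally))
  if (any(tally < 0)) stop("negative element count in formula", call. = FALSE)
  structure(tally, class = "element_tally",
            balanceable = !any(names(tally) %in% PSEUDO_ELEMENTS))
}

#' Format an element tally as a formula string in Hill order
#'
#' Carbon first, then hydrogen, then all remaining elements alphabetically
#' (the Hill system). Inverse of [parse_formula()] on canonical input.
#'
#' @param tally an `element_tally` or named numeric vector.
#' @return a formula string.
#' @export
format_formula <- function(tally) {
  if (length(tally) == 0L) return("")
  syms <- names(tally)
  ord <- order(match(syms, c("C", "H"), nomatch = 3L), syms)
  syms <- syms[ord]
  cnts <- unname(unclass(tally))[ord]
  fmt1 <- function(x) {
    if (abs(x - round(x)) < 1e-9) {
      if (round(x) == 1) "" else format(round(x), scientific = FALSE)
    } else {
      format(x, scientific = FALSE)
    }
  }
  paste0(syms, vapply(cnts, fmt1, ""), collapse = "")
}

#' Molecular weight of an element tally
#'
#' @param tally an `element_tally` (see [parse_formula()]) or formula string.
#' @return molecular weight in g/mol.
#' @export
molecular_weight <- function(tally) {
  if (is.character(tally)) tally <- parse_formula(tally)
  if (!isTRUE(attr(tally, "balanceable"))) {
    stop("formula contains pseudo-elements (R/X); molecular weight undefined",
         call. = FALSE)
  }
  syms <- names(tally)
  unknown <- setdiff(syms, names(ATOMIC_MASSES))
  if (length(unknown) > 0L) {
    stop("no atomic mass known for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(ATOMIC_MASSES[syms] * unclass(tally))
}

#' @export
print.element_tally <- function(x, ...) {
  cat("<element tally> ", format_formula(x),
      if (!isTRUE(attr(x, "balanceable"))) " [non-balanceable]", "\n", sep = "")
  invisible(x)
}
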