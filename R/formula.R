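# Molecular formulas as element-count vectors with a canonical Hill-order
# string rendering. MS-Ready neutral formulas need no isotopes, charges or
# nesting, so the grammar is deliberately small: (Element)(count?) repeated.

# Monoisotopic masses of the elements the synthetic generator and formula
# arithmetic support. Values in Da.
ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  F  = 18.99840320,
  Cl = 34.96885271,
  Br = 78.9183376
)

#' Parse a molecular formula string
#'
#' Accepts Hill-order style strings such as `"C10H12N2O"` with one- or
#' two-letter element symbols and optional counts. No isotope labels,
#' charges, or parentheses.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts (all `>= 1`), in Hill
#'   order (C, H, then alphabetical).
#' @examples
#' parse_formula("C10H12N2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  s <- trimws(formula)
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: '", formula, "'")
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  if (any(counts < 1L)) stop("element count must be >= 1 in '", formula, "'")
  out <- tapply(counts, elems, sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  hill_order(counts)
}

# Order a named count vector in Hill convention: C first, H second (when C
# present), remaining elements alphabetical.
hill_order <- function(counts) {
  elems <- names(counts)
  rest <- sort(setdiff(elems, c("C", "H")))
  ord <- if ("C" %in% elems) c("C", intersect("H", elems), rest) else sort(elems)
  counts[ord]
}

#' Render element counts as a canonical formula string
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A Hill-order formula string; counts of 1 are omitted.
#' @examples
#' formula_string(c(C = 10L, H = 12L, N = 2L, O = 1L))
#' @export
formula_string <- function(counts) {
  counts <- hill_order(counts)
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' Canonicalize a formula string
#'
#' Parse-and-rerender, so that e.g. `"OC10N2H12"` and `"C10H12N2O"` compare
#' equal as strings. Vectorized.
#'
#' @param formula Character vector of formula strings.
#' @return Character vector of canonical Hill-order renderings.
#' @export
canonical_formula <- function(formula) {
  vapply(formula, function(f) formula_string(parse_formula(f)), character(1),
         USE.NAMES = FALSE)
}

#' Monoisotopic mass of a formula
#'
#' Sum of element monoisotopic masses weighted by counts. Vectorized over
#' formula strings.
#'
#' @param formula Character vector of formula strings.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' formula_mass("CH4") # 16.0313
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    unknown <- setdiff(names(counts), names(ELEMENT_MASSES))
    if (length(unknown)) {
      stop("no monoisotopic mass for element(s): ", paste(unknown, collapse = ", "))
    }
    sum(ELEMENT_MASSES[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
}
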