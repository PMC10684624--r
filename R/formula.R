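# Elemental-composition substrate: parsing, Hill-notation formatting and
# monoisotopic / nominal mass arithmetic. Everything downstream (adduct
# calculus, enumeration, derivatization series) is built on these.

# Monoisotopic masses of the most abundant isotope (IUPAC/AME, Da).
# C is exactly 12 by definition of the unified atomic mass unit.
.element_data <- data.frame(
  symbol = c("C", "H", "N", "O", "F", "Na", "Si", "P", "S", "Cl"),
  monoisotopic_mass = c(
    12.0,          # 12C, exact
    1.00782503,    # 1H
    14.00307401,   # 14N
    15.99491462,   # 16O
    18.99840316,   # 19F
    22.98976928,   # 23Na
    27.97692653,   # 28Si
    30.97376200,   # 31P
    31.97207117,   # 32S
    34.96885268    # 35Cl
  ),
  stringsAsFactors = FALSE
)
.element_data$nominal_mass <- as.integer(round(.element_data$monoisotopic_mass))

.mono_mass <- stats::setNames(.element_data$monoisotopic_mass, .element_data$symbol)
.nom_mass  <- stats::setNames(.element_data$nominal_mass, .element_data$symbol)

# CODATA electron mass in Da; toggling the correction shifts every singly
# charged m/z by exactly this amount.
.electron_mass <- 0.00054857991

#' Supported elements and their masses
#'
#' Returns the built-in element table: monoisotopic mass of the most
#' abundant isotope (Da; carbon exactly 12) and its integer nominal mass.
#'
#' @return A data frame with columns `symbol`, `monoisotopic_mass`,
#'   `nominal_mass`.
#' @export
#' @examples
#' element_table()
element_table <- function() .element_data

.hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

new_chem_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    counts <- counts[.hill_order(names(counts))]
  }
  structure(as.integer(counts), names = names(counts), class = "chem_formula")
}

#' Parse an elemental formula string
#'
#' Parses Hill-style formula text such as `"C45H80O7Si5"` into an element
#' count vector. A symbol without a trailing integer means count 1; repeated
#' symbols are summed. Unknown elements, zero counts and text that does not
#' tokenize (e.g. a lowercase-leading symbol) are rejected with an error
#' naming the offending token.
#'
#' @param text A single formula string, or an already-parsed `chem_formula`
#'   (returned unchanged).
#' @return A `chem_formula`: a named integer vector of element counts in
#'   Hill order.
#' @export
#' @examples
#' parse_formula("C45H80O7Si5")
#' parse_formula("H2O")
parse_formula <- function(text) {
  if (inherits(text, "chem_formula")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  s <- trimws(text)
  if (s == "") return(new_chem_formula(integer(0)))

  pos <- 1L
  syms <- character(0)
  cnts <- integer(0)
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexpr("^([A-Z][a-z]?)([0-9]*)", rest))
    if (length(m) == 0L || m == "") {
      stop(sprintf("malformed formula '%s': cannot parse at '%s'", text, rest),
           call. = FALSE)
    }
    sym <- sub("[0-9]*$", "", m)
    num <- sub("^[A-Za-z]+", "", m)
    if (!sym %in% names(.mono_mass)) {
      stop(sprintf("unknown element '%s' in formula '%s'", sym, text),
           call. = FALSE)
    }
    cnt <- if (num == "") 1L else suppressWarnings(as.integer(num))
    if (is.na(cnt) || cnt <= 0L) {
      stop(sprintf("invalid count '%s' for element '%s' in formula '%s'",
                   num, sym, text), call. = FALSE)
    }
    syms <- c(syms, sym)
    cnts <- c(cnts, cnt)
    pos <- pos + nchar(m)
  }
  tot <- tapply(cnts, syms, sum)
  new_chem_formula(stats::setNames(as.integer(tot), names(tot)))
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  n <- unclass(x)
  paste0(names(n), ifelse(n == 1L, "", n), collapse = "")
}

#' @export
as.character.chem_formula <- function(x, ...) format(x)

#' @export
print.chem_formula <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<chem_formula> (empty)\n")
  } else {
    cat(sprintf("<chem_formula> %s  monoisotopic %.5f Da, nominal %d Da\n",
                format(x), monoisotopic_mass(x), nominal_mass(x)))
  }
  invisible(x)
}

.element_count <- function(f, sym) {
  if (sym %in% names(f)) unclass(f)[[sym]] else 0L
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times the most-abundant-isotope mass over all elements.
#' The empty formula has mass 0.
#'
#' @param f Formula string or `chem_formula`.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C45H80O7Si5") # ~872.475
monoisotopic_mass <- function(f) {
  f <- parse_formula(f)
  if (length(f) == 0L) return(0)
  missing <- setdiff(names(f), names(.mono_mass))
  if (length(missing)) {
    stop(sprintf("element(s) missing from mass table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sum(unclass(f) * .mono_mass[names(f)])
}

#' Nominal (integer) mass of a formula
#'
#' @inheritParams monoisotopic_mass
#' @return Integer mass in Da.
#' @export
#' @examples
#' nominal_mass("C15H22O11") # 378
nominal_mass <- function(f) {
  f <- parse_formula(f)
  if (length(f) == 0L) return(0L)
  missing <- setdiff(names(f), names(.nom_mass))
  if (length(missing)) {
    stop(sprintf("element(s) missing from mass table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.integer(sum(unclass(f) * .nom_mass[names(f)]))
}

#' Combine two formulas element-wise
#'
#' Computes `a + multiplier * b` element-wise. A negative multiplier
#' performs subtraction and errors if any element count would go below
#' zero (composition underflow).
#'
#' @param a,b Formula strings or `chem_formula` objects.
#' @param multiplier Integer scale applied to `b` (may be negative).
#' @return A `chem_formula`.
#' @export
#' @examples
#' formula_combine("C15H23O11", "C6H14Si", 4) # C39H79O11Si4
formula_combine <- function(a, b, multiplier = 1L) {
  a <- parse_formula(a)
  b <- parse_formula(b)
  multiplier <- as.integer(multiplier)
  syms <- union(names(a), names(b))
  res <- vapply(syms, function(s) {
    .element_count(a, s) + multiplier * .element_count(b, s)
  }, integer(1))
  if (any(res < 0L)) {
    bad <- syms[res < 0L]
    stop(sprintf("composition underflow: element(s) %s would have negative count",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  new_chem_formula(res)
}

#' Ring-plus-double-bond equivalents
#'
#' Valence-based unsaturation count with Si treated as tetravalent (like
#' C), N and P trivalent, and halogens monovalent:
#' `rdbe = 1 + C + Si - (H + F + Cl)/2 + (N + P)/2`.
#'
#' @inheritParams monoisotopic_mass
#' @return A half-integer RDBE value.
#' @export
rdbe <- function(f) {
  f <- parse_formula(f)
  g <- function(s) .element_count(f, s)
  1 + g("C") + g("Si") - (g("H") + g("F") + g("Cl")) / 2 + (g("N") + g("P")) / 2
}

# Canonical Hill string; used for formula equality everywhere.
.canon <- function(x) format(parse_formula(x))
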