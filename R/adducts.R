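# ESI adduct rules and the EI radical-cation rule: how a neutral becomes
# an observed ion. Only |charge| = 1 species are supported.

.adduct_registry <- list(
  "[M+H]+" = list(name = "[M+H]+", multimer = 1L, delta = c(H = 1L),
                  charge = 1L, polarity = "positive"),
  "[M-H]-" = list(name = "[M-H]-", multimer = 1L, delta = c(H = -1L),
                  charge = -1L, polarity = "negative"),
  "[M+Na]+" = list(name = "[M+Na]+", multimer = 1L, delta = c(Na = 1L),
                   charge = 1L, polarity = "positive"),
  "[2M+Na]+" = list(name = "[2M+Na]+", multimer = 2L, delta = c(Na = 1L),
                    charge = 1L, polarity = "positive"),
  "[M]+." = list(name = "[M]+.", multimer = 1L, delta = integer(0),
                 charge = 1L, polarity = "positive")
)

#' Registered adduct rules
#'
#' The built-in ionization rules: protonation `[M+H]+`, deprotonation
#' `[M-H]-`, sodiation `[M+Na]+`, the sodiated dimer `[2M+Na]+`, and the
#' EI radical cation `[M]+.`. Each rule holds a multimer count, an
#' element delta (signed counts), a signed unit charge and a polarity.
#'
#' @return Named list of adduct rule definitions.
#' @export
adduct_rules <- function() .adduct_registry

.get_adduct <- function(x) {
  if (is.list(x) && all(c("multimer", "delta", "charge", "polarity") %in% names(x))) {
    return(x)
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("adduct must be a rule name or a rule definition list", call. = FALSE)
  }
  # tolerate the typographic minus sign used in print
  key <- gsub("−|–", "-", x)
  rule <- .adduct_registry[[key]]
  if (is.null(rule)) {
    stop(sprintf("unknown adduct '%s'; registered: %s", x,
                 paste(names(.adduct_registry), collapse = ", ")),
         call. = FALSE)
  }
  rule
}

.delta_mono <- function(rule) {
  d <- rule$delta
  if (!length(d)) return(0)
  sum(d * .mono_mass[names(d)])
}

.delta_nominal <- function(rule) {
  d <- rule$delta
  if (!length(d)) return(0L)
  as.integer(sum(d * .nom_mass[names(d)]))
}

#' Elemental composition of an ion
#'
#' `multimer * neutral + delta` for the given adduct rule; e.g. the
#' `[M-H]-` ion of C26H38O6Si2 is C26H37O6Si2. Errors if a delta would
#' drive any element negative (e.g. deprotonating an H-free neutral).
#'
#' @param neutral Formula string or `chem_formula` of the neutral.
#' @param adduct Adduct rule name (see [adduct_rules()]) or rule list.
#' @return A `chem_formula` for the ion's elemental composition.
#' @export
ion_formula <- function(neutral, adduct = "[M+H]+") {
  rule <- .get_adduct(adduct)
  f <- parse_formula(neutral)
  if (length(f) == 0L) stop("neutral formula is empty", call. = FALSE)
  base <- new_chem_formula(unclass(f) * rule$multimer)
  d <- rule$delta
  if (!length(d)) return(base)
  formula_combine(base, new_chem_formula(abs(d)), if (d[[1]] < 0) -1L else 1L)
}

#' Predicted m/z of a neutral under an adduct rule
#'
#' In accurate mode, `m/z = (multimer * M + mass(delta) - q * m_e) / |q|`
#' where the electron mass is subtracted for net positive ions and added
#' for net negative ions when `electron_correction` is on. Nominal mode
#' uses integer masses and no electron term.
#'
#' @inheritParams ion_formula
#' @param electron_correction Apply the electron-mass term (default TRUE).
#' @param resolution `"accurate"` (monoisotopic) or `"nominal"` (integer).
#' @return m/z in Da per unit charge (integer in nominal mode).
#' @export
#' @examples
#' ion_mz("C45H80O7Si5", "[M+H]+")   # ~873.48
#' ion_mz("C15H10O7", "[M]+.", resolution = "nominal") # 302
ion_mz <- function(neutral, adduct = "[M+H]+", electron_correction = TRUE,
                   resolution = c("accurate", "nominal")) {
  resolution <- match.arg(resolution)
  rule <- .get_adduct(adduct)
  f <- parse_formula(neutral)
  if (length(f) == 0L) stop("neutral formula is empty", call. = FALSE)
  ion_formula(f, rule)  # validates composition (e.g. H available for [M-H]-)
  if (resolution == "nominal") {
    return(as.integer(rule$multimer * nominal_mass(f) + .delta_nominal(rule)))
  }
  m <- rule$multimer * monoisotopic_mass(f) + .delta_mono(rule)
  if (electron_correction) m <- m - sign(rule$charge) * .electron_mass
  m / abs(rule$charge)
}

#' Mass error between observed and theoretical m/z
#'
#' Signed observed-minus-theoretical error in mDa and ppm.
#'
#' @param observed,theoretical Positive m/z values (vectorized).
#' @return A `mass_error` object with `absolute_mda` and `relative_ppm`.
#' @export
#' @examples
#' mass_error(100.0010, 100.0000) # +1.0 mDa, +10 ppm
mass_error <- function(observed, theoretical) {
  if (any(!is.finite(observed)) || any(!is.finite(theoretical)) ||
      any(observed <= 0) || any(theoretical <= 0)) {
    stop("observed and theoretical m/z must be positive and finite",
         call. = FALSE)
  }
  structure(list(
    absolute_mda = (observed - theoretical) * 1000,
    relative_ppm = (observed - theoretical) / theoretical * 1e6
  ), class = "mass_error")
}

#' @export
print.mass_error <- function(x, ...) {
  cat(sprintf("<mass_error> %+.2f mDa (%+.2f ppm)\n",
              x$absolute_mda, x$relative_ppm))
  invisible(x)
}
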