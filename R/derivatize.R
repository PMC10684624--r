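# Derivatization arithmetic: silylated formulas, predicted m/z series
# across derivatization degrees, and the hydroxyl-count constraint that
# an observed maximum degree implies.

#' Formula of an n-times derivatized parent
#'
#' `parent + n * site_delta`. Each silylation replaces one acidic proton,
#' so the parent must carry at least `n` hydrogens.
#'
#' @param parent Formula string or `chem_formula` of the underivatized
#'   neutral.
#' @param reagent Reagent name or `deriv_reagent` (see [get_reagent()]).
#' @param n Derivatization degree (integer >= 0).
#' @return A `chem_formula`.
#' @export
#' @examples
#' derivatized_formula("C15H10O7", "TBDMS", 5) # C45H80O7Si5
derivatized_formula <- function(parent, reagent, n) {
  reagent <- get_reagent(reagent)
  parent <- parse_formula(parent)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L) {
    stop("derivatization degree n must be a single integer >= 0",
         call. = FALSE)
  }
  if (.element_count(parent, "H") < n) {
    stop(sprintf("parent %s has only %d H; cannot replace %d acidic protons",
                 format(parent), .element_count(parent, "H"), n),
         call. = FALSE)
  }
  formula_combine(parent, reagent$site_delta, n)
}

#' Predict a derivatization series of m/z values
#'
#' One predicted m/z per derivatization degree under a single adduct
#' rule. Accurate mode uses monoisotopic masses through [ion_mz()];
#' nominal mode uses integer masses (TBDMS spacing exactly 114, TMS 72).
#'
#' @inheritParams derivatized_formula
#' @param degrees Integer vector of degrees (>= 0, non-empty).
#' @param adduct Adduct rule name or list.
#' @param resolution `"accurate"` or `"nominal"`.
#' @param electron_correction Passed to [ion_mz()] in accurate mode.
#' @return Data frame with columns `degree`, `formula`, `mz`.
#' @export
#' @examples
#' predict_series("C15H10O7", "TBDMS", 2:5, adduct = "[M]+.",
#'                resolution = "nominal") # 530 644 758 872
predict_series <- function(parent, reagent, degrees, adduct = "[M]+.",
                           resolution = c("accurate", "nominal"),
                           electron_correction = TRUE) {
  resolution <- match.arg(resolution)
  degrees <- as.integer(degrees)
  if (!length(degrees) || anyNA(degrees) || any(degrees < 0L)) {
    stop("degrees must be a non-empty vector of integers >= 0",
         call. = FALSE)
  }
  reagent <- get_reagent(reagent)
  parent <- parse_formula(parent)
  rows <- lapply(degrees, function(d) {
    f <- derivatized_formula(parent, reagent, d)
    data.frame(degree = d, formula = format(f),
               mz = ion_mz(f, adduct, electron_correction = electron_correction,
                           resolution = resolution),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hydroxyl-count constraint implied by observed derivatization degrees
#'
#' If a compound is seen derivatized up to `n` times, it must carry at
#' least `n` silylatable sites; for hydroxyl-targeting reagents each
#' site is an OH, so the parent needs at least `n` oxygen atoms.
#'
#' @param observed_degrees Non-empty set of observed degrees (>= 0).
#' @param reagent Reagent name or `deriv_reagent`.
#' @return A `site_constraint`: list with `min_sites` and `implied_min_O`.
#' @export
#' @examples
#' infer_site_constraint(c(1, 4), "TBDMS") # at least 4 sites, >= 4 O
infer_site_constraint <- function(observed_degrees, reagent) {
  degrees <- as.integer(observed_degrees)
  if (!length(degrees) || anyNA(degrees) || any(degrees < 0L)) {
    stop("observed_degrees must be a non-empty set of integers >= 0",
         call. = FALSE)
  }
  reagent <- get_reagent(reagent)
  min_sites <- max(degrees)
  implied_min_O <- if ("hydroxyl" %in% reagent$target_groups) min_sites else 0L
  structure(list(min_sites = min_sites, implied_min_O = implied_min_O),
            class = "site_constraint")
}

#' @export
print.site_constraint <- function(x, ...) {
  cat(sprintf("<site_constraint> at least %d silylatable site(s); implied O >= %d\n",
              x$min_sites, x$implied_min_O))
  invisible(x)
}
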