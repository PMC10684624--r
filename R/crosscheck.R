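# Derivatization-series cross-check: intersect candidate formula sets
# across an underivatized ion and n-times-derivatized ions of the same
# parent. A degree-0 candidate survives only if, at every observed
# degree n, the candidate plus exactly n site deltas is present in that
# ion's candidate set — with optional silicon-count and site-count
# (oxygen/hydrogen floor) constraints. Matching is exact element-wise
# arithmetic, never a mass window, so the narrowing is deterministic.

#' Construct an observed-ion record
#'
#' One measured ion with its adduct, its derivatization-degree
#' hypothesis, and a candidate formula set (enumerated via
#' [enumerate_formulas()] or supplied externally, e.g. from a printed
#' table of vendor assignments).
#'
#' @param mz Observed m/z (may be `NA` when candidates are supplied).
#' @param degree Derivatization-degree hypothesis (integer >= 0).
#' @param adduct Adduct rule name or list.
#' @param candidates A character vector of ion-form formulas, a
#'   `candidate_set`, or a data frame with columns `formula` and
#'   optionally `error_mda`.
#' @param polarity `"positive"` or `"negative"`; defaults to the
#'   adduct's polarity.
#' @return An `observed_ion` object.
#' @export
observed_ion <- function(mz = NA_real_, degree = 0L, adduct = "[M+H]+",
                         candidates = NULL, polarity = NULL) {
  rule <- .get_adduct(adduct)
  degree <- as.integer(degree)
  if (is.na(degree) || degree < 0L) {
    stop("degree must be an integer >= 0", call. = FALSE)
  }
  cand <- .normalize_candidates(candidates)
  if (!is.null(cand) && nrow(cand) == 0L) {
    stop("supplied candidate set is empty", call. = FALSE)
  }
  structure(list(mz = mz, degree = degree, adduct = rule,
                 polarity = polarity %||% rule$polarity,
                 candidates = cand),
            class = "observed_ion")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.normalize_candidates <- function(candidates) {
  if (is.null(candidates)) return(NULL)
  if (inherits(candidates, "candidate_set")) {
    df <- candidates$candidates[, c("formula", "error_mda")]
  } else if (is.data.frame(candidates)) {
    stopifnot("formula" %in% names(candidates))
    df <- data.frame(formula = candidates$formula,
                     error_mda = if ("error_mda" %in% names(candidates))
                       candidates$error_mda else NA_real_,
                     stringsAsFactors = FALSE)
  } else if (is.character(candidates)) {
    df <- data.frame(formula = candidates,
                     error_mda = rep(NA_real_, length(candidates)),
                     stringsAsFactors = FALSE)
  } else {
    stop("candidates must be a character vector, data frame or candidate_set",
         call. = FALSE)
  }
  df$formula <- vapply(df$formula, .canon, character(1))
  rownames(df) <- NULL
  df
}

#' Build observed-ion records from printed candidate lists
#'
#' Turns externally supplied per-degree formula lists (such as the
#' vendor-assigned ion compositions printed in a publication table) into
#' `observed_ion` records. The printed formulas are trusted as-is: no
#' m/z re-verification is attempted.
#'
#' @param rows A list of `list(degree =, formulas =, mz =, adduct =)`
#'   entries (`mz`, `adduct` optional; adduct defaults to `"[M+H]+"`).
#' @return List of `observed_ion` objects.
#' @export
#' @examples
#' ions <- candidates_from_table(list(
#'   list(degree = 0, formulas = c("C15H23O11", "C22H19O6")),
#'   list(degree = 1, formulas = c("C21H37O11Si", "C28H33O6Si"))
#' ))
candidates_from_table <- function(rows) {
  if (!is.list(rows) || !length(rows)) {
    stop("rows must be a non-empty list of (degree, formulas) entries",
         call. = FALSE)
  }
  lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    if (is.null(r$degree) || is.null(r$formulas) || !length(r$formulas)) {
      stop(sprintf("row %d must supply a degree and at least one formula", i),
           call. = FALSE)
    }
    parsed <- tryCatch(vapply(r$formulas, .canon, character(1)),
                       error = function(e) {
                         stop(sprintf("row %d: %s", i, conditionMessage(e)),
                              call. = FALSE)
                       })
    observed_ion(mz = r$mz %||% NA_real_, degree = r$degree,
                 adduct = r$adduct %||% "[M+H]+", candidates = parsed)
  })
}

#' Cross-check candidate sets across derivatization degrees
#'
#' The central narrowing step. A degree-0 candidate `F` survives iff:
#' (a) for every ion with degree `n > 0`, `F + n * site_delta` is a
#' member of that ion's candidate set (exact element-wise match);
#' (b) if `parent_si_free`, `F` contains no Si and every degree-`n`
#' match contains exactly `n` Si; (c) if `apply_site_constraint`, the
#' candidate has at least `max(degree)` oxygens and its neutral form at
#' least that many hydrogens (the replaceable acidic protons must
#' exist). Eliminations record the first violated rule, checked in the
#' order (a), (b), (c).
#'
#' @param ions List of [observed_ion()] records sharing one parent
#'   hypothesis; exactly one must have degree 0, degrees must be unique,
#'   and every ion needs a candidate set.
#' @param reagent Reagent name or `deriv_reagent`.
#' @param parent_si_free Apply the silicon-count rule (natural-product
#'   parents are Si-free; each silylation adds exactly one Si).
#' @param apply_site_constraint Apply the oxygen/hydrogen floor.
#' @param min_sites Optional override of the site floor; defaults to the
#'   maximum observed degree.
#' @param candidate_form `"ion"` when candidate formulas are ion
#'   compositions (the usual vendor output), `"neutral"` otherwise.
#' @return A `crosscheck_result`: survivors ranked by summed |mass
#'   error| along the chain (ties by Hill string), per-survivor chains,
#'   and an elimination table naming the first failed constraint
#'   (`missing-pair`, `silicon-count`, `oxygen-floor`, `hydrogen-floor`).
#' @export
crosscheck <- function(ions, reagent = "TBDMS", parent_si_free = TRUE,
                       apply_site_constraint = TRUE, min_sites = NULL,
                       candidate_form = c("ion", "neutral")) {
  candidate_form <- match.arg(candidate_form)
  reagent <- get_reagent(reagent)
  if (!is.list(ions) || !length(ions) ||
      !all(vapply(ions, inherits, logical(1), "observed_ion"))) {
    stop("ions must be a non-empty list of observed_ion records",
         call. = FALSE)
  }
  degrees <- vapply(ions, `[[`, integer(1), "degree")
  if (sum(degrees == 0L) != 1L) {
    stop("configuration error: exactly one ion must have degree 0",
         call. = FALSE)
  }
  if (anyDuplicated(degrees)) {
    stop("configuration error: duplicate derivatization degrees",
         call. = FALSE)
  }
  if (any(vapply(ions, function(x) is.null(x$candidates), logical(1)))) {
    stop("every ion needs a candidate set (enumerate or supply one)",
         call. = FALSE)
  }
  ions <- ions[order(degrees)]
  degrees <- sort(degrees)
  base_ion <- ions[[1]]
  deriv_ions <- ions[-1]
  floor_n <- as.integer(min_sites %||% max(degrees))
  delta <- reagent$site_delta

  # hydrogen count of the neutral form of a candidate
  neutral_h <- function(f, rule) {
    h <- .element_count(f, "H")
    if (candidate_form == "neutral") return(h)
    dh <- if ("H" %in% names(rule$delta)) rule$delta[["H"]] else 0L
    (h - dh) / rule$multimer
  }

  survivors <- character(0)
  chains <- list()
  chain_err <- numeric(0)
  elim <- list()

  for (j in seq_len(nrow(base_ion$candidates))) {
    fstr <- base_ion$candidates$formula[j]
    f <- parse_formula(fstr)
    rule_violated <- NULL
    detail <- NA_integer_
    chain <- data.frame(degree = 0L, formula = fstr,
                        error_mda = base_ion$candidates$error_mda[j],
                        stringsAsFactors = FALSE)

    # (a) series pairing at every derivatized degree
    for (ion in deriv_ions) {
      expected <- tryCatch(formula_combine(f, delta, ion$degree),
                           error = function(e) NULL)
      hit <- if (is.null(expected)) integer(0) else
        which(ion$candidates$formula == format(expected))
      if (!length(hit)) {
        rule_violated <- "missing-pair"
        detail <- ion$degree
        break
      }
      chain <- rbind(chain, data.frame(
        degree = ion$degree, formula = format(expected),
        error_mda = ion$candidates$error_mda[hit[1]],
        stringsAsFactors = FALSE))
    }

    # (b) silicon counts
    if (is.null(rule_violated) && parent_si_free) {
      si_parent <- .element_count(f, "Si")
      si_matches <- vapply(seq_len(nrow(chain)), function(i) {
        .element_count(parse_formula(chain$formula[i]), "Si") == chain$degree[i]
      }, logical(1))
      if (si_parent != 0L || !all(si_matches)) rule_violated <- "silicon-count"
    }

    # (c) oxygen / hydrogen floors from the observed maximum degree
    if (is.null(rule_violated) && apply_site_constraint) {
      if (.element_count(f, "O") < floor_n) {
        rule_violated <- "oxygen-floor"
      } else if (neutral_h(f, base_ion$adduct) < floor_n) {
        rule_violated <- "hydrogen-floor"
      }
    }

    if (is.null(rule_violated)) {
      survivors <- c(survivors, fstr)
      chains[[fstr]] <- chain
      chain_err <- c(chain_err, sum(abs(chain$error_mda), na.rm = TRUE))
    } else {
      elim[[length(elim) + 1L]] <- data.frame(
        formula = fstr, rule = rule_violated, degree = detail,
        stringsAsFactors = FALSE)
    }
  }

  ord <- order(chain_err, survivors)
  survivors <- survivors[ord]
  chains <- chains[survivors]
  eliminated <- if (length(elim)) do.call(rbind, elim) else
    data.frame(formula = character(0), rule = character(0),
               degree = integer(0), stringsAsFactors = FALSE)

  structure(list(surviving_parents = survivors, chains = chains,
                 eliminated = eliminated, candidate_form = candidate_form,
                 reagent = reagent$name, min_sites = floor_n,
                 settings = list(parent_si_free = parent_si_free,
                                 apply_site_constraint = apply_site_constraint)),
            class = "crosscheck_result")
}

#' @export
print.crosscheck_result <- function(x, ...) {
  n <- length(x$surviving_parents)
  cat(sprintf("<crosscheck_result> %d surviving parent formula(s) [%s form, reagent %s]\n",
              n, x$candidate_form, x$reagent))
  for (f in x$surviving_parents) {
    ch <- x$chains[[f]]
    cat(sprintf("  %s  (chain: %s)\n", f,
                paste(sprintf("%dx -> %s", ch$degree, ch$formula),
                      collapse = "; ")))
  }
  if (nrow(x$eliminated)) {
    cat("eliminated:\n")
    for (i in seq_len(nrow(x$eliminated))) {
      e <- x$eliminated[i, ]
      extra <- if (e$rule == "missing-pair" && !is.na(e$degree))
        sprintf(" at degree %d", e$degree) else ""
      cat(sprintf("  %s  [%s%s]\n", e$formula, e$rule, extra))
    }
  }
  invisible(x)
}
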