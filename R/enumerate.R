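# Candidate-formula enumeration from accurate mass: exhaustive recursive
# descent over elements in decreasing-mass order with residual-mass
# interval pruning. Exact within the element bounds, and cheap at the
# bound sizes used for small-molecule work, so it can be compared 1:1
# against a brute-force grid oracle.

#' Default element bounds for enumeration
#'
#' Covers silylated natural products with slack: C 0-60, H 0-100,
#' O 0-20, Si 0-6, N 0-5.
#'
#' @return Named list of `c(min, max)` count ranges.
#' @export
default_element_bounds <- function() {
  list(C = c(0L, 60L), H = c(0L, 100L), O = c(0L, 20L),
       Si = c(0L, 6L), N = c(0L, 5L))
}

#' Enumerate candidate elemental compositions for an observed m/z
#'
#' Finds every neutral composition within the element bounds whose ion
#' m/z under `adduct` lies within `tolerance_mda` of `target_mz`
#' (`adduct = NULL` treats the target as a neutral monoisotopic mass).
#' Candidates are reported in ion form together with their neutral form,
#' theoretical m/z, signed errors and RDBE, sorted by |error| with ties
#' broken by Hill string.
#'
#' @param target_mz Observed m/z (or neutral mass if `adduct` is NULL).
#' @param tolerance_mda Match window half-width in mDa (> 0).
#' @param adduct Adduct rule name, rule list, or NULL for a bare neutral
#'   mass target.
#' @param bounds Named list of `c(min, max)` counts per element.
#' @param rdbe_range Optional `c(min, max)` RDBE filter (off by default:
#'   vendor-style searches often keep chemically implausible rows).
#' @param require_integer_rdbe Keep only integer-RDBE candidates.
#' @param electron_correction Passed to [ion_mz()].
#' @param max_candidates Hard cap; exceeding it is an error (never silent
#'   truncation).
#' @return A `candidate_set`: list with the search settings and a
#'   `candidates` data frame (`formula`, `neutral_formula`,
#'   `theoretical_mz`, `error_mda`, `error_ppm`, `rdbe`).
#' @export
#' @examples
#' cs <- enumerate_formulas(114.0865, tolerance_mda = 5,
#'                          bounds = list(C = c(0, 10), H = c(0, 30),
#'                                        O = c(0, 5), Si = c(0, 2)))
#' cs$candidates$formula
enumerate_formulas <- function(target_mz, tolerance_mda = 5, adduct = NULL,
                               bounds = default_element_bounds(),
                               rdbe_range = NULL,
                               require_integer_rdbe = FALSE,
                               electron_correction = TRUE,
                               max_candidates = 10000L) {
  if (!length(bounds)) {
    stop("configuration error: element bounds are empty", call. = FALSE)
  }
  if (!is.numeric(tolerance_mda) || tolerance_mda <= 0) {
    stop("tolerance_mda must be > 0", call. = FALSE)
  }
  syms <- names(bounds)
  unknown <- setdiff(syms, names(.mono_mass))
  if (length(unknown)) {
    stop(sprintf("unknown element(s) in bounds: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  lims <- lapply(bounds, function(b) {
    b <- as.integer(b)
    if (length(b) != 2L || any(b < 0L) || b[1] > b[2]) {
      stop("each bound must be c(min, max) with 0 <= min <= max",
           call. = FALSE)
    }
    b
  })

  rule <- if (is.null(adduct)) NULL else .get_adduct(adduct)
  if (is.null(rule)) {
    m_lo <- target_mz - tolerance_mda / 1000
    m_hi <- target_mz + tolerance_mda / 1000
  } else {
    e <- if (electron_correction) sign(rule$charge) * .electron_mass else 0
    neutral_total <- target_mz * abs(rule$charge) + e - .delta_mono(rule)
    m_lo <- (neutral_total - tolerance_mda / 1000) / rule$multimer
    m_hi <- (neutral_total + tolerance_mda / 1000) / rule$multimer
  }

  ord <- order(.mono_mass[syms], decreasing = TRUE)
  syms <- syms[ord]
  lims <- lims[ord]
  mass <- unname(.mono_mass[syms])
  mins <- vapply(lims, `[`, integer(1), 1L)
  maxs <- vapply(lims, `[`, integer(1), 2L)
  k <- length(syms)
  # max mass attainable by elements after position i
  maxrest <- rev(cumsum(rev(c(maxs * mass, 0))))[-1]

  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 256L)
  acc$n <- 0L
  eps <- 1e-9

  descend <- function(i, counts, lo, hi) {
    if (i > k) {
      if (lo <= eps && hi >= -eps) {
        acc$n <- acc$n + 1L
        if (acc$n > max_candidates) {
          stop(sprintf(paste0("candidate overflow: more than %d compositions ",
                              "match; tighten the tolerance or bounds"),
                       max_candidates), call. = FALSE)
        }
        if (acc$n > length(acc$rows)) {
          length(acc$rows) <- 2L * length(acc$rows)
        }
        acc$rows[[acc$n]] <- counts
      }
      return(invisible(NULL))
    }
    m <- mass[i]
    cmin <- max(mins[i], as.integer(ceiling((lo - maxrest[i]) / m - eps)))
    cmax <- min(maxs[i], as.integer(floor(hi / m + eps)))
    if (cmin > cmax) return(invisible(NULL))
    for (cc in cmin:cmax) {
      counts[i] <- cc
      descend(i + 1L, counts, lo - cc * m, hi - cc * m)
    }
    invisible(NULL)
  }
  descend(1L, integer(k), m_lo, m_hi)

  rows <- if (acc$n) acc$rows[seq_len(acc$n)] else list()
  recs <- lapply(rows, function(counts) {
    neutral <- new_chem_formula(stats::setNames(counts, syms))
    if (length(neutral) == 0L) return(NULL)
    ionf <- if (is.null(rule)) neutral else {
      tryCatch(ion_formula(neutral, rule), error = function(e) NULL)
    }
    if (is.null(ionf)) return(NULL)  # e.g. deprotonating an H-free neutral
    theo <- if (is.null(rule)) monoisotopic_mass(neutral) else {
      ion_mz(neutral, rule, electron_correction = electron_correction)
    }
    r <- rdbe(neutral)
    if (!is.null(rdbe_range) && (r < rdbe_range[1] || r > rdbe_range[2])) {
      return(NULL)
    }
    if (require_integer_rdbe && abs(r - round(r)) > 1e-9) return(NULL)
    err <- mass_error(target_mz, theo)
    data.frame(formula = format(ionf), neutral_formula = format(neutral),
               theoretical_mz = theo, error_mda = err$absolute_mda,
               error_ppm = err$relative_ppm, rdbe = r,
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  cand <- if (length(recs)) do.call(rbind, recs) else {
    data.frame(formula = character(0), neutral_formula = character(0),
               theoretical_mz = numeric(0), error_mda = numeric(0),
               error_ppm = numeric(0), rdbe = numeric(0),
               stringsAsFactors = FALSE)
  }
  cand <- cand[order(abs(cand$error_mda), cand$formula), , drop = FALSE]
  rownames(cand) <- NULL

  structure(list(target_mz = target_mz, tolerance_mda = tolerance_mda,
                 adduct = if (is.null(rule)) NULL else rule$name,
                 bounds = bounds, candidates = cand),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> target m/z %.4f (+/- %g mDa, %s): %d candidate(s)\n",
              x$target_mz, x$tolerance_mda,
              if (is.null(x$adduct)) "neutral mass" else x$adduct,
              nrow(x$candidates)))
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates, 10L), digits = 8)
    if (nrow(x$candidates) > 10L) cat("...\n")
  }
  invisible(x)
}
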