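# Peak <-> prediction matching, EI neutral-loss prediction, and the
# semi-quantitative derivatization-efficiency statistics.

#' Known recurrent background ions
#'
#' Recurrent silylation-workflow background ions: the trimethylsilyl
#' column-bleed fragment near m/z 73.10 and unassigned recurrent ions at
#' 191.00, 207.10 and 281.10. Shipped as a tentative annotation list;
#' nothing is ever subtracted automatically.
#'
#' @return Data frame with columns `label`, `mz`.
#' @export
background_ions <- function() {
  data.frame(
    label = c("TMS column bleed (tentative)", "background 191 (unassigned)",
              "background 207 (unassigned)", "background 281 (unassigned)"),
    mz = c(73.10, 191.00, 207.10, 281.10),
    stringsAsFactors = FALSE)
}

#' Match predicted species to observed peaks
#'
#' Each prediction is matched to the nearest peak within tolerance (at
#' most one peak per prediction); if two peaks are exactly equidistant
#' the more intense one wins. Unmatched predictions are reported
#' separately; empty matches are a valid result, never an error.
#'
#' @param p A `peaklist`.
#' @param predictions Data frame with columns `label` and `mz`, or a
#'   named numeric vector of predicted m/z.
#' @param tolerance_da Match half-window in Da; defaults to 0.005
#'   (5 mDa) for accurate-mass lists and 0.5 for unit resolution.
#' @return A `peak_annotations` object with `matched` (peak_index,
#'   peak_mz, intensity, label, predicted_mz, error_mda) and `unmatched`
#'   data frames.
#' @export
annotate_peaks <- function(p, predictions, tolerance_da = NULL) {
  stopifnot(inherits(p, "peaklist"))
  if (is.numeric(predictions)) {
    predictions <- data.frame(
      label = names(predictions) %||% sprintf("prediction_%d",
                                              seq_along(predictions)),
      mz = as.numeric(predictions), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(predictions) ||
      !all(c("label", "mz") %in% names(predictions)) ||
      !nrow(predictions)) {
    stop("predictions must be a non-empty data frame with label and mz",
         call. = FALSE)
  }
  tol <- tolerance_da %||% if (p$resolution == "accurate") 0.005 else 0.5

  matched <- list()
  unmatched <- list()
  for (i in seq_len(nrow(predictions))) {
    pred <- predictions$mz[i]
    lab <- predictions$label[i]
    if (!length(p)) {
      unmatched[[length(unmatched) + 1L]] <-
        data.frame(label = lab, predicted_mz = pred, stringsAsFactors = FALSE)
      next
    }
    d <- abs(p$mz - pred)
    within <- which(d <= tol + 1e-12)
    if (!length(within)) {
      unmatched[[length(unmatched) + 1L]] <-
        data.frame(label = lab, predicted_mz = pred, stringsAsFactors = FALSE)
      next
    }
    dmin <- min(d[within])
    best <- within[d[within] <= dmin + 1e-12]
    if (length(best) > 1L) best <- best[which.max(p$intensity[best])]
    matched[[length(matched) + 1L]] <- data.frame(
      peak_index = best, peak_mz = p$mz[best], intensity = p$intensity[best],
      label = lab, predicted_mz = pred,
      error_mda = (p$mz[best] - pred) * 1000, stringsAsFactors = FALSE)
  }
  empty_m <- data.frame(peak_index = integer(0), peak_mz = numeric(0),
                        intensity = numeric(0), label = character(0),
                        predicted_mz = numeric(0), error_mda = numeric(0),
                        stringsAsFactors = FALSE)
  empty_u <- data.frame(label = character(0), predicted_mz = numeric(0),
                        stringsAsFactors = FALSE)
  structure(list(
    matched = if (length(matched)) do.call(rbind, matched) else empty_m,
    unmatched = if (length(unmatched)) do.call(rbind, unmatched) else empty_u,
    tolerance_da = tol), class = "peak_annotations")
}

#' @export
print.peak_annotations <- function(x, ...) {
  cat(sprintf("<peak_annotations> %d matched, %d unmatched (tolerance %.4g Da)\n",
              nrow(x$matched), nrow(x$unmatched), x$tolerance_da))
  if (nrow(x$matched)) print(x$matched, digits = 8)
  invisible(x)
}

#' Predict EI fragments for a (derivatized) species
#'
#' Emits the molecular radical cation `[M]+.` and one `[M - loss]+`
#' fragment per characteristic reagent loss. Losses flagged generic in
#' the registry (methyl) apply to any species; silyl-specific losses
#' (the TBDMS t-butyl) require at least one Si. A loss that is not
#' subtractable from the composition is omitted with a warning. The
#' reagent's reporter ion, if defined, is appended.
#'
#' @param species Formula string or `chem_formula` of the ionized
#'   species (parent or derivatized form).
#' @param reagent Reagent name or `deriv_reagent`.
#' @param resolution `"nominal"` (integer, default for quadrupole EI)
#'   or `"accurate"`.
#' @return Data frame with columns `label`, `formula`, `mz`.
#' @export
#' @examples
#' predict_ei_fragments("C45H80O7Si5", "TBDMS") # 872, 857, 815
predict_ei_fragments <- function(species, reagent,
                                 resolution = c("nominal", "accurate")) {
  resolution <- match.arg(resolution)
  reagent <- get_reagent(reagent)
  species <- parse_formula(species)
  if (length(species) == 0L) stop("species formula is empty", call. = FALSE)

  frag_mz <- function(f) {
    if (resolution == "nominal") nominal_mass(f)
    else monoisotopic_mass(f) - .electron_mass
  }
  rows <- list(data.frame(label = "[M]+.", formula = format(species),
                          mz = frag_mz(species), stringsAsFactors = FALSE))
  has_si <- .element_count(species, "Si") >= 1L
  for (loss in reagent$ei_losses) {
    if (!loss$generic && !has_si) next
    frag <- tryCatch(formula_combine(species, loss$formula, -1L),
                     error = function(e) NULL)
    if (is.null(frag)) {
      warning(sprintf("loss %s not subtractable from %s; fragment omitted",
                      loss$label, format(species)), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("[M-%s]+", loss$label), formula = format(frag),
      mz = frag_mz(frag), stringsAsFactors = FALSE)
  }
  if (!is.na(reagent$reporter_ion_mz)) {
    rep_mz <- if (resolution == "nominal") round(reagent$reporter_ion_mz)
              else reagent$reporter_ion_mz
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("%s+ reporter", reagent$name), formula = NA_character_,
      mz = rep_mz, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Derivatization efficiency from a peak list
#'
#' Matches predicted quasi-molecular ions of the parent at degrees
#' `0..max_degree` (for every listed adduct) against the peak list and
#' reports the underivatized:derivatized intensity ratio. A ratio of
#' zero means complete derivatization; if no derivatized species is
#' detected at all, the ratio is undefined and flagged rather than
#' divided through.
#'
#' @param p A `peaklist`.
#' @param parent Underivatized neutral formula.
#' @param reagent Reagent name or `deriv_reagent`.
#' @param adducts Character vector of adduct rule names to match.
#' @param max_degree Highest derivatization degree considered (>= 1).
#' @param tolerance_da Match half-window (default by resolution, as in
#'   [annotate_peaks()]).
#' @param label Free-form label (`"batch"`, `"flow"`, ...).
#' @return An `efficiency_report`: `underivatized_intensity`,
#'   `derivatized_intensity`, `ratio`, `status`
#'   (`"ok"`, `"complete-derivatization"`, `"no-derivatized-signal"`),
#'   `label` and the underlying annotations.
#' @export
derivatization_ratio <- function(p, parent, reagent, adducts = c("[M-H]-"),
                                 max_degree, tolerance_da = NULL,
                                 label = "other") {
  stopifnot(inherits(p, "peaklist"))
  max_degree <- as.integer(max_degree)
  if (is.na(max_degree) || max_degree < 1L) {
    stop("max_degree must be an integer >= 1", call. = FALSE)
  }
  reagent <- get_reagent(reagent)
  parent <- parse_formula(parent)
  preds <- list()
  for (d in 0:max_degree) {
    f <- tryCatch(derivatized_formula(parent, reagent, d),
                  error = function(e) NULL)
    if (is.null(f)) next
    for (a in adducts) {
      mz <- tryCatch(ion_mz(f, a), error = function(e) NA_real_)
      if (is.na(mz)) next
      preds[[length(preds) + 1L]] <- data.frame(
        label = sprintf("degree%d %s", d, a), degree = d, mz = mz,
        stringsAsFactors = FALSE)
    }
  }
  preds <- do.call(rbind, preds)
  ann <- annotate_peaks(p, preds[, c("label", "mz")],
                        tolerance_da = tolerance_da)
  deg <- preds$degree[match(ann$matched$label, preds$label)]
  u <- sum(ann$matched$intensity[deg == 0L])
  v <- sum(ann$matched$intensity[deg >= 1L])
  status <- if (v == 0) "no-derivatized-signal"
            else if (u == 0) "complete-derivatization"
            else "ok"
  ratio <- if (v == 0) NA_real_ else u / v
  structure(list(underivatized_intensity = u, derivatized_intensity = v,
                 ratio = ratio, status = status, label = label,
                 annotations = ann), class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> [%s] underivatized %.4g : derivatized %.4g",
              x$label, x$underivatized_intensity, x$derivatized_intensity))
  if (x$status == "ok") {
    cat(sprintf(" -> ratio %.4g:1\n", x$ratio))
  } else {
    cat(sprintf(" -> %s\n", x$status))
  }
  invisible(x)
}

#' Relative efficiency of two derivatization runs
#'
#' How many times more complete one run is than another, as the ratio of
#' their underivatized:derivatized ratios. Reported raw and rounded to
#' two significant figures. An undefined or zero denominator ratio is
#' flagged rather than propagated silently.
#'
#' @param batch,flow `efficiency_report` objects (or bare numeric
#'   ratios); the factor is `batch_ratio / flow_ratio`.
#' @return An `efficiency_factor` object with `factor`, `factor_2sf`
#'   and `status`.
#' @export
#' @examples
#' efficiency_factor(9.08, 0.366) # 24.81 raw, 25 at 2 s.f.
efficiency_factor <- function(batch, flow) {
  get_ratio <- function(x) {
    if (inherits(x, "efficiency_report")) x$ratio else as.numeric(x)
  }
  b <- get_ratio(batch)
  f <- get_ratio(flow)
  if (is.na(b) || b <= 0) {
    stop("batch ratio is undefined or non-positive", call. = FALSE)
  }
  if (is.na(f) || f == 0) {
    return(structure(list(factor = Inf, factor_2sf = Inf,
                          status = "undefined-flow-ratio"),
                     class = "efficiency_factor"))
  }
  raw <- b / f
  structure(list(factor = raw, factor_2sf = signif(raw, 2), status = "ok"),
            class = "efficiency_factor")
}

#' @export
print.efficiency_factor <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<efficiency_factor> %.4f raw (%g at 2 s.f.)\n",
                x$factor, x$factor_2sf))
  } else {
    cat(sprintf("<efficiency_factor> %s\n", x$status))
  }
  invisible(x)
}
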