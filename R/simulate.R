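# Synthetic-spectrum generators. Real raw spectra for silylation
# experiments are rarely deposited, so the pipeline is exercised on
# simulated data whose generative parameters are known exactly:
# Gaussian m/z calibration error, mean-one lognormal multiplicative
# intensity noise, and optional uniform background peaks.

#' Specification for an ESI spectrum simulation
#'
#' Defaults emulate a flow-derivatization HR-MS experiment on quercetin:
#' TBDMS chemistry on a 5-site parent, residual underivatized signal at
#' weight 0.366 against a dominant 4x-derivatized species at weight 1,
#' deprotonated ions, 25 scans, 1 mDa calibration sigma and 10 %
#' intensity CV.
#'
#' @param parent Underivatized neutral formula.
#' @param reagent Reagent name or `deriv_reagent`.
#' @param n_sites Number of silylatable sites on the parent.
#' @param degree_weights Non-negative weights over degrees `0..n_sites`
#'   (length `n_sites + 1`); the expected underivatized:derivatized
#'   intensity ratio is `w[0] / sum(w[1..n_sites])`.
#' @param adduct_weights Named non-negative weights over registered
#'   adducts; all adducts must share one polarity.
#' @param base_intensity Intensity scale (arbitrary units).
#' @param calibration_sigma_mda Gaussian m/z error SD in mDa.
#' @param intensity_cv Coefficient of variation of the mean-one
#'   lognormal intensity noise.
#' @param n_background Uniform-random background peaks per scan.
#' @param include_known_background Also inject the recurrent background
#'   ions from [background_ions()] into every scan.
#' @param n_scans Number of scans to simulate.
#' @param seed RNG seed; the full output is reproducible from it.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(parent = "C15H10O7", reagent = "TBDMS",
                            n_sites = 5L,
                            degree_weights = c(0.366, 0, 0, 0, 1, 0),
                            adduct_weights = c("[M-H]-" = 1),
                            base_intensity = 1000,
                            calibration_sigma_mda = 1,
                            intensity_cv = 0.1,
                            n_background = 5L,
                            include_known_background = FALSE,
                            n_scans = 25L, seed = 1L) {
  parent <- parse_formula(parent)
  reagent <- get_reagent(reagent)
  n_sites <- as.integer(n_sites)
  if (length(degree_weights) != n_sites + 1L) {
    stop("degree_weights must have length n_sites + 1 (degrees 0..n_sites)",
         call. = FALSE)
  }
  if (any(degree_weights < 0) || sum(degree_weights) <= 0) {
    stop("degree_weights must be non-negative with positive sum",
         call. = FALSE)
  }
  if (is.null(names(adduct_weights)) || any(adduct_weights < 0) ||
      sum(adduct_weights) <= 0) {
    stop("adduct_weights must be a named non-negative vector with positive sum",
         call. = FALSE)
  }
  pols <- unique(vapply(names(adduct_weights),
                        function(a) .get_adduct(a)$polarity, character(1)))
  if (length(pols) != 1L) {
    stop("all simulated adducts must share one polarity", call. = FALSE)
  }
  if (calibration_sigma_mda < 0 || intensity_cv < 0) {
    stop("calibration_sigma_mda and intensity_cv must be >= 0", call. = FALSE)
  }
  if (as.integer(n_scans) < 1L) stop("n_scans must be >= 1", call. = FALSE)
  structure(list(parent = parent, reagent = reagent, n_sites = n_sites,
                 degree_weights = degree_weights,
                 adduct_weights = adduct_weights,
                 base_intensity = base_intensity,
                 calibration_sigma_mda = calibration_sigma_mda,
                 intensity_cv = intensity_cv,
                 n_background = as.integer(n_background),
                 include_known_background = isTRUE(include_known_background),
                 n_scans = as.integer(n_scans), seed = as.integer(seed),
                 polarity = pols),
            class = "simulation_spec")
}

#' Simulate ESI HR-MS scans of a derivatization mixture
#'
#' One peak per (degree, adduct) pair with positive weight and per scan:
#' m/z is the theoretical value plus Gaussian calibration error,
#' intensity is `base * degree_weight * adduct_weight` times mean-one
#' lognormal noise; optional uniform background peaks are added. With
#' zero noise every peak sits exactly on its theoretical m/z, so the
#' generative ratio and parent are recoverable exactly.
#'
#' @param spec A [simulation_spec()].
#' @return An `esi_simulation`: `scans` (list of `peaklist`) and
#'   `truth` (species table with theoretical m/z and expected
#'   intensities, plus the generative underivatized:derivatized ratio).
#' @export
simulate_esi <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  degrees <- which(spec$degree_weights > 0) - 1L
  adducts <- names(spec$adduct_weights)[spec$adduct_weights > 0]
  species <- do.call(rbind, lapply(degrees, function(d) {
    f <- derivatized_formula(spec$parent, spec$reagent, d)
    do.call(rbind, lapply(adducts, function(a) {
      data.frame(degree = d, adduct = a, formula = format(f),
                 mz = ion_mz(f, a),
                 expected_intensity = spec$base_intensity *
                   spec$degree_weights[d + 1L] * spec$adduct_weights[[a]],
                 stringsAsFactors = FALSE)
    }))
  }))
  w <- spec$degree_weights
  truth_ratio <- if (sum(w[-1]) > 0) w[1] / sum(w[-1]) else NA_real_

  sigma <- spec$calibration_sigma_mda / 1000
  cv <- spec$intensity_cv
  sdlog <- sqrt(log(1 + cv^2))
  mlog <- -sdlog^2 / 2
  mz_lo <- max(50, min(species$mz) - 50)
  mz_hi <- max(species$mz) + 50
  mode <- if (spec$polarity == "positive") "ESI-pos" else "ESI-neg"

  scans <- lapply(seq_len(spec$n_scans), function(s) {
    mzv <- species$mz + stats::rnorm(nrow(species), 0, sigma)
    iv <- species$expected_intensity *
      if (cv > 0) stats::rlnorm(nrow(species), mlog, sdlog) else 1
    if (spec$n_background > 0L) {
      mzv <- c(mzv, stats::runif(spec$n_background, mz_lo, mz_hi))
      iv <- c(iv, stats::runif(spec$n_background, 0,
                               0.02 * spec$base_intensity))
    }
    if (spec$include_known_background) {
      bg <- background_ions()
      mzv <- c(mzv, bg$mz)
      iv <- c(iv, rep(0.05 * spec$base_intensity, nrow(bg)))
    }
    ord <- order(mzv)
    mzv <- mzv[ord]
    iv <- iv[ord]
    # merge coincident m/z so the strict-ordering invariant holds
    grp <- cumsum(c(1L, as.integer(diff(mzv) > 1e-9)))
    mzv2 <- vapply(split(mzv, grp), `[`, numeric(1), 1L)
    iv2 <- vapply(split(iv, grp), sum, numeric(1))
    peaklist(mzv2, iv2, mode = mode, resolution = "accurate",
             metadata = list(scan = s, seed = spec$seed))
  })
  structure(list(scans = scans,
                 truth = list(species = species, ratio = truth_ratio,
                              spec = spec)),
            class = "esi_simulation")
}

#' @export
print.esi_simulation <- function(x, ...) {
  cat(sprintf("<esi_simulation> %d scan(s), %d species, true ratio %s\n",
              length(x$scans), nrow(x$truth$species),
              format(x$truth$ratio, digits = 4)))
  invisible(x)
}

#' Simulate a unit-resolution EI spectrum
#'
#' Molecular radical cation plus the reagent's characteristic loss peaks
#' at nominal m/z (with optional Gaussian unit-resolution jitter), and a
#' trimethylsilyl column-bleed peak at m/z 73 (on by default, as it is
#' near-ubiquitous in silylation GC-MS). The default intensity profile
#' makes the t-butyl-loss fragment the base peak, reflecting the greater
#' stability of the t-butyl radical relative to methyl.
#'
#' @param parent Underivatized neutral formula.
#' @param reagent Reagent name or `deriv_reagent`.
#' @param degree Derivatization degree of the simulated species.
#' @param base_intensity Intensity scale.
#' @param intensity_profile Optional named relative intensities keyed by
#'   fragment label (defaults: `[M]+.` 0.5, `[M-CH3]+` 0.3,
#'   `[M-C4H9]+` 1.0, others 0.2).
#' @param jitter_sd Gaussian m/z jitter SD in Da (0 = exact nominal).
#' @param include_bleed Add the m/z 73 column-bleed peak.
#' @param seed RNG seed.
#' @return A unit-resolution EI `peaklist`; the generating fragment
#'   table is attached as `metadata$truth`.
#' @export
#' @examples
#' simulate_ei("C15H10O7", "TBDMS", degree = 5)$mz # 73 815 857 872
simulate_ei <- function(parent, reagent, degree, base_intensity = 100,
                        intensity_profile = NULL, jitter_sd = 0,
                        include_bleed = TRUE, seed = 1L) {
  set.seed(as.integer(seed))
  reagent <- get_reagent(reagent)
  species <- derivatized_formula(parent, reagent, degree)
  frags <- predict_ei_fragments(species, reagent, resolution = "nominal")
  if (include_bleed && !any(abs(frags$mz - 73) < 0.5)) {
    frags <- rbind(frags, data.frame(label = "TMS column bleed",
                                     formula = NA_character_, mz = 73,
                                     stringsAsFactors = FALSE))
  }
  default_rel <- c("[M]+." = 0.5, "[M-CH3]+" = 0.3, "[M-C4H9]+" = 1.0)
  rel <- default_rel[frags$label]
  rel[is.na(rel)] <- 0.2
  if (!is.null(intensity_profile)) {
    hit <- frags$label %in% names(intensity_profile)
    rel[hit] <- intensity_profile[frags$label[hit]]
  }
  mzv <- frags$mz + if (jitter_sd > 0)
    stats::rnorm(nrow(frags), 0, jitter_sd) else 0
  iv <- base_intensity * as.numeric(rel)
  ord <- order(mzv)
  peaklist(mzv[ord], iv[ord], mode = "EI", resolution = "unit",
           metadata = list(truth = frags[ord, ], seed = seed,
                           species = format(species)))
}
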