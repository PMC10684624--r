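# Derivatization reagents are data, not code: the shipped registry
# (inst/extdata/reagents.yaml) defines TBDMS and TMS; users can supply
# their own definitions in the same shape.

.reagent_cache <- new.env(parent = emptyenv())

.load_reagent_registry <- function() {
  if (!is.null(.reagent_cache$registry)) return(.reagent_cache$registry)
  path <- system.file("extdata", "reagents.yaml", package = "silylms")
  if (path == "") stop("shipped reagent registry not found", call. = FALSE)
  raw <- yaml::read_yaml(path)
  reg <- lapply(raw, .as_reagent)
  .reagent_cache$registry <- reg
  reg
}

.as_reagent <- function(x) {
  stopifnot(is.list(x), !is.null(x$name), !is.null(x$site_delta))
  delta <- parse_formula(x$site_delta)
  if (.element_count(delta, "Si") < 1L) {
    stop(sprintf("silyl reagent '%s' must add at least one Si per site",
                 x$name), call. = FALSE)
  }
  losses <- lapply(x$ei_losses, function(l) {
    list(label = l$label, formula = parse_formula(l$formula),
         generic = isTRUE(l$generic))
  })
  structure(list(
    name = x$name,
    description = x$description,
    site_delta = delta,
    target_groups = unlist(x$target_groups),
    ei_losses = losses,
    reporter_ion_mz = if (is.null(x$reporter_ion_mz)) NA_real_ else
      as.numeric(x$reporter_ion_mz)
  ), class = "deriv_reagent")
}

#' Silylation reagent registry
#'
#' Reagents shipped with the package (TBDMS and TMS), read from the
#' packaged YAML registry. Each entry records the net per-site
#' composition delta, the functional groups it targets, characteristic
#' EI radical losses and an optional reporter ion m/z.
#'
#' @return Named list of `deriv_reagent` objects.
#' @export
#' @examples
#' names(silyl_reagents())
silyl_reagents <- function() .load_reagent_registry()

#' Look up (or validate) a derivatization reagent
#'
#' @param reagent A registry name (`"TBDMS"`, `"TMS"`), a `deriv_reagent`,
#'   or a list in the registry shape.
#' @return A `deriv_reagent` object.
#' @export
get_reagent <- function(reagent) {
  if (inherits(reagent, "deriv_reagent")) return(reagent)
  if (is.character(reagent) && length(reagent) == 1L) {
    reg <- .load_reagent_registry()
    r <- reg[[reagent]]
    if (is.null(r)) {
      stop(sprintf("unknown reagent '%s'; registered: %s", reagent,
                   paste(names(reg), collapse = ", ")), call. = FALSE)
    }
    return(r)
  }
  if (is.list(reagent)) return(.as_reagent(reagent))
  stop("reagent must be a name, a deriv_reagent, or a definition list",
       call. = FALSE)
}

#' @export
print.deriv_reagent <- function(x, ...) {
  cat(sprintf("<deriv_reagent> %s: +%s per site (nominal +%d)\n",
              x$name, format(x$site_delta), nominal_mass(x$site_delta)))
  if (length(x$ei_losses)) {
    cat("  EI losses:",
        paste(vapply(x$ei_losses, function(l)
          sprintf("-%s (%d)", l$label, nominal_mass(l$formula)),
          character(1)), collapse = ", "), "\n")
  }
  if (!is.na(x$reporter_ion_mz)) {
    cat(sprintf("  reporter ion m/z %.4f\n", x$reporter_ion_mz))
  }
  invisible(x)
}
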