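# Peak-list container and I/O. A peak list is centroided data: strictly
# increasing m/z with non-negative intensities, plus acquisition mode
# and resolution so downstream matching can pick sensible tolerances.

#' Construct a peak list
#'
#' @param mz Strictly increasing numeric vector of m/z values.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param mode Acquisition mode: `"ESI-pos"`, `"ESI-neg"` or `"EI"`.
#' @param resolution `"accurate"` (HR-MS) or `"unit"` (quadrupole EI).
#' @param metadata Free-form named list.
#' @return A `peaklist` object.
#' @export
#' @examples
#' peaklist(c(100.1, 200.2), c(50, 10), mode = "EI", resolution = "unit")
peaklist <- function(mz, intensity, mode = c("ESI-pos", "ESI-neg", "EI"),
                     resolution = c("accurate", "unit"), metadata = list()) {
  mode <- match.arg(mode)
  resolution <- match.arg(resolution)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz)) {
    if (anyNA(mz) || anyNA(intensity)) {
      stop("mz and intensity must not contain NA", call. = FALSE)
    }
    bad_sort <- which(diff(mz) <= 0)
    if (length(bad_sort)) {
      stop(sprintf("mz must be strictly increasing; violated at row(s) %s",
                   paste(bad_sort + 1L, collapse = ", ")), call. = FALSE)
    }
    bad_int <- which(intensity < 0)
    if (length(bad_int)) {
      stop(sprintf("intensities must be >= 0; violated at row(s) %s",
                   paste(bad_int, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(mz = mz, intensity = intensity, mode = mode,
                 resolution = resolution, metadata = metadata),
            class = "peaklist")
}

#' @export
length.peaklist <- function(x) length(x$mz)

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %d peak(s), %s, %s resolution\n",
              length(x), x$mode, x$resolution))
  if (length(x)) {
    df <- data.frame(mz = x$mz, intensity = x$intensity)
    print(utils::head(df, 8L), digits = 8)
    if (length(x) > 8L) cat("...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.peaklist <- function(x, ...) {
  data.frame(mz = x$mz, intensity = x$intensity)
}

.guess_format <- function(path) {
  if (grepl("\\.msp$", path, ignore.case = TRUE)) "msp" else "csv"
}

#' Read a peak list from CSV or MSP
#'
#' CSV needs a header with `mz,intensity` columns. MSP is the NIST-style
#' text format (`Name:` / `Num Peaks:` header followed by `mz intensity`
#' pairs); a file with several MSP blocks returns a list of peak lists.
#' Unsorted or negative rows are a validation error naming the rows.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"msp"`.
#' @param mode,resolution Passed to [peaklist()]; MSP defaults to
#'   unit-resolution EI, CSV to accurate-mass ESI.
#' @return A `peaklist` (or list of them for multi-block MSP).
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "msp"),
                          mode = NULL, resolution = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("mz", "intensity") %in% names(df))) {
      stop("CSV peak list needs header columns 'mz' and 'intensity'",
           call. = FALSE)
    }
    peaklist(df$mz, df$intensity,
             mode = mode %||% "ESI-pos",
             resolution = resolution %||% "accurate",
             metadata = list(source = path))
  } else {
    .read_msp(path, mode = mode %||% "EI", resolution = resolution %||% "unit")
  }
}

.read_msp <- function(path, mode, resolution) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      name <- trimws(sub("^Name:", "", ln, ignore.case = TRUE))
      j <- i + 1L
      npeaks <- NA_integer_
      while (j <= length(lines)) {
        lj <- trimws(lines[j])
        if (grepl("^Num ?Peaks:", lj, ignore.case = TRUE)) {
          npeaks <- as.integer(trimws(sub("^Num ?Peaks:", "", lj,
                                          ignore.case = TRUE)))
          break
        }
        if (grepl("^Name:", lj, ignore.case = TRUE)) break
        j <- j + 1L
      }
      if (is.na(npeaks)) {
        stop(sprintf("MSP block '%s' has no 'Num Peaks:' line", name),
             call. = FALSE)
      }
      vals <- numeric(0)
      j <- j + 1L
      while (j <= length(lines) && length(vals) < 2L * npeaks) {
        lj <- trimws(lines[j])
        if (nzchar(lj)) {
          toks <- strsplit(lj, "[;,[:space:]]+")[[1]]
          toks <- toks[nzchar(toks)]
          vals <- c(vals, suppressWarnings(as.numeric(toks)))
        }
        j <- j + 1L
      }
      if (anyNA(vals) || length(vals) < 2L * npeaks) {
        stop(sprintf("MSP block '%s': expected %d peaks, found %d",
                     name, npeaks, floor(length(vals) / 2)), call. = FALSE)
      }
      mzv <- vals[seq(1L, 2L * npeaks, by = 2L)]
      iv <- vals[seq(2L, 2L * npeaks, by = 2L)]
      ord <- order(mzv)
      blocks[[length(blocks) + 1L]] <- peaklist(
        mzv[ord], iv[ord], mode = mode, resolution = resolution,
        metadata = list(name = name, source = path))
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(blocks)) stop("no MSP spectra found", call. = FALSE)
  if (length(blocks) == 1L) blocks[[1]] else blocks
}

#' Write a peak list to CSV or MSP
#'
#' @param p A `peaklist`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"msp"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(p, path, format = c("auto", "csv", "msp")) {
  stopifnot(inherits(p, "peaklist"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (format == "csv") {
    df <- data.frame(mz = format(p$mz, digits = 12, trim = TRUE,
                                 scientific = FALSE),
                     intensity = format(p$intensity, digits = 12, trim = TRUE,
                                        scientific = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    name <- p$metadata$name %||% "spectrum"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("Name: %s", name),
                 sprintf("Num Peaks: %d", length(p)),
                 sprintf("%s %s",
                         format(p$mz, digits = 12, trim = TRUE,
                                scientific = FALSE),
                         format(p$intensity, digits = 12, trim = TRUE,
                                scientific = FALSE))), con)
  }
  invisible(path)
}

#' Average several scans into one peak list
#'
#' Pools peaks from all scans, merges pooled peaks that fall within
#' `bin_tolerance_mda` of their neighbour (single-linkage along the m/z
#' axis), and reports the intensity-weighted mean m/z and the mean
#' intensity per scan (a peak absent from a scan contributes 0 to the
#' mean).
#'
#' @param scans Non-empty list of `peaklist` objects with a common mode.
#' @param bin_tolerance_mda Merge window in mDa.
#' @return A single averaged `peaklist`.
#' @export
average_spectra <- function(scans, bin_tolerance_mda = 5) {
  if (inherits(scans, "peaklist")) scans <- list(scans)
  if (!length(scans) || !all(vapply(scans, inherits, logical(1), "peaklist"))) {
    stop("scans must be a non-empty list of peaklist objects", call. = FALSE)
  }
  modes <- unique(vapply(scans, `[[`, character(1), "mode"))
  if (length(modes) != 1L) {
    stop("all scans must share one acquisition mode", call. = FALSE)
  }
  n_scans <- length(scans)
  mz <- unlist(lapply(scans, `[[`, "mz"))
  intensity <- unlist(lapply(scans, `[[`, "intensity"))
  if (!length(mz)) {
    return(peaklist(numeric(0), numeric(0), mode = modes,
                    resolution = scans[[1]]$resolution,
                    metadata = list(n_scans_averaged = n_scans)))
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  tol <- bin_tolerance_mda / 1000
  grp <- cumsum(c(1L, as.integer(diff(mz) > tol)))
  agg_mz <- vapply(split(seq_along(mz), grp), function(idx) {
    w <- intensity[idx]
    if (sum(w) > 0) sum(mz[idx] * w) / sum(w) else mean(mz[idx])
  }, numeric(1))
  agg_int <- vapply(split(intensity, grp), sum, numeric(1)) / n_scans
  ord2 <- order(agg_mz)
  peaklist(agg_mz[ord2], agg_int[ord2], mode = modes,
           resolution = scans[[1]]$resolution,
           metadata = list(n_scans_averaged = n_scans,
                           bin_tolerance_mda = bin_tolerance_mda))
}
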