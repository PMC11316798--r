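# CSV readers/writers for the tabular dialects the analysis stages exchange.

#' Read a chromatogram CSV
#'
#' Expects a header with columns `volume_mL,absorbance` (UTF-8, '.' decimal
#' separator).
#'
#' @param path CSV path.
#' @param wavelength nominal detection wavelength (nm), metadata.
#' @param label sample label; defaults to the file stem.
#' @return a [Chromatogram-class].
#' @export
readChromatogramCsv <- function(path, wavelength = 280, label = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("volume_mL", "absorbance") %in% names(d)))
    stop("expected columns volume_mL,absorbance in ", path)
  Chromatogram(d$volume_mL, d$absorbance, wavelength = wavelength,
               label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname readChromatogramCsv
#' @param x a [Chromatogram-class] to write.
#' @export
writeChromatogramCsv <- function(x, path) {
  utils::write.csv(data.frame(volume_mL = x@volume, absorbance = x@absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a time-resolved spectral series CSV
#'
#' Accepts either the long dialect (`time_s,wavelength_nm,absorbance`) or
#' the wide dialect (first column `wavelength_nm`, remaining column names the
#' time stamps in seconds). The dialect is auto-detected from the header.
#'
#' @param path CSV path.
#' @return a [SpectralSeries-class].
#' @export
readSpectralSeriesCsv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (all(c("time_s", "wavelength_nm", "absorbance") %in% names(d))) {
    wl <- sort(unique(d$wavelength_nm))
    tt <- sort(unique(d$time_s))
    A <- matrix(NA_real_, length(wl), length(tt))
    A[cbind(match(d$wavelength_nm, wl), match(d$time_s, tt))] <- d$absorbance
    if (anyNA(A)) stop("long-format series is not a complete grid")
    return(SpectralSeries(wl, tt, A))
  }
  if (names(d)[1] == "wavelength_nm") {
    tt <- as.numeric(names(d)[-1])
    if (anyNA(tt)) stop("wide-format column names must be time stamps (s)")
    return(SpectralSeries(d$wavelength_nm, tt,
                          as.matrix(d[, -1, drop = FALSE])))
  }
  stop("unrecognized spectral CSV dialect in ", path)
}

#' @rdname readSpectralSeriesCsv
#' @param x a [SpectralSeries-class] to write (wide dialect).
#' @export
writeSpectralSeriesCsv <- function(x, path) {
  d <- data.frame(wavelength_nm = x@wavelengths, x@absorbance,
                  check.names = FALSE)
  names(d)[-1] <- as.character(x@times)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read kinetics traces from CSV
#'
#' Expects columns `time_s,signal,replicate_id` and optionally `species`.
#'
#' @param path CSV path.
#' @return list of [KineticsTrace-class], one per replicate id.
#' @export
readKineticsCsv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "signal", "replicate_id") %in% names(d)))
    stop("expected columns time_s,signal,replicate_id in ", path)
  if ("species" %in% names(d)) d$species[is.na(d$species)] <- ""
  key <- if ("species" %in% names(d) && any(nzchar(d$species)))
    interaction(d$replicate_id, d$species, drop = TRUE) else d$replicate_id
  lapply(unname(split(d, key)), function(g) {
    g <- g[order(g$time_s), ]
    KineticsTrace(g$time_s, g$signal, replicateId = as.character(g$replicate_id[1]),
                  species = if ("species" %in% names(g))
                    as.character(g$species[1]) else "")
  })
}

#' @rdname readKineticsCsv
#' @param traces list of [KineticsTrace-class] to write.
#' @export
writeKineticsCsv <- function(traces, path) {
  if (is(traces, "KineticsTrace")) traces <- list(traces)
  d <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = tr@times, signal = tr@signal,
               replicate_id = tr@replicateId, species = tr@species)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
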