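#' Multi-peak fat spectrum
#'
#' A fat spectrum is a set of triglyceride resonance peaks, each with a
#' chemical shift relative to water (ppm, signed; the dominant methylene
#' peak sits near -3.4 ppm) and a relative proton-density amplitude.
#' Amplitudes must be strictly positive and sum to one.
#'
#' @param shift_ppm numeric vector of chemical shifts relative to water in
#'   ppm (signed).
#' @param amplitude numeric vector of relative amplitudes, positive,
#'   summing to 1 within `1e-9`.
#' @return an object of class `fat_spectrum`.
#' @seealso [default_fat_spectrum()], [read_fat_spectrum()]
#' @examples
#' fat_spectrum(shift_ppm = -3.4, amplitude = 1)
#' @export
fat_spectrum <- function(shift_ppm, amplitude) {
  shift_ppm <- as.numeric(shift_ppm)
  amplitude <- as.numeric(amplitude)
  if (length(shift_ppm) < 1L || length(shift_ppm) != length(amplitude)) {
    stop("spectrum needs at least one peak with matching shift/amplitude lengths")
  }
  if (any(!is.finite(shift_ppm)) || any(!is.finite(amplitude))) {
    stop("spectrum shifts and amplitudes must be finite")
  }
  if (any(amplitude <= 0)) {
    stop("spectrum amplitudes must be strictly positive")
  }
  if (abs(sum(amplitude) - 1) > 1e-9) {
    stop("spectrum amplitudes must sum to 1 (within 1e-9); got ",
         format(sum(amplitude), digits = 12))
  }
  structure(list(shift_ppm = shift_ppm, amplitude = amplitude),
            class = "fat_spectrum")
}

#' Default 7-peak triglyceride spectrum
#'
#' The packaged default is the widely used 7-peak condensed triglyceride
#' spectrum (shifts relative to water: -3.80, -3.40, -3.10, -2.68, -2.46,
#' -1.95, -0.50 ppm with amplitudes 0.087, 0.693, 0.128, 0.004, 0.039,
#' 0.010, 0.039).  It is a configuration default, not a measured property
#' of any particular scanner; replace it via [fat_spectrum()] or
#' [read_fat_spectrum()] when a site-calibrated spectrum is available.
#'
#' @return a `fat_spectrum` with 7 peaks.
#' @export
default_fat_spectrum <- function() {
  fat_spectrum(
    shift_ppm = c(-3.80, -3.40, -3.10, -2.68, -2.46, -1.95, -0.50),
    amplitude = c(0.087, 0.693, 0.128, 0.004, 0.039, 0.010, 0.039)
  )
}

#' Read / write a fat spectrum as YAML
#'
#' The on-disk format is a YAML list of `{ppm, amplitude}` entries.
#'
#' @param path file path.
#' @return `read_fat_spectrum()` returns a `fat_spectrum`;
#'   `write_fat_spectrum()` returns `path` invisibly.
#' @export
read_fat_spectrum <- function(path) {
  raw <- yaml::read_yaml(path)
  peaks <- raw$peaks %||% raw
  fat_spectrum(
    shift_ppm = vapply(peaks, function(p) as.numeric(p$ppm), numeric(1)),
    amplitude = vapply(peaks, function(p) as.numeric(p$amplitude), numeric(1))
  )
}

#' @rdname read_fat_spectrum
#' @param spectrum a `fat_spectrum`.
#' @export
write_fat_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fat_spectrum"))
  peaks <- Map(function(p, a) list(ppm = p, amplitude = a),
               spectrum$shift_ppm, spectrum$amplitude)
  yaml::write_yaml(list(peaks = unname(peaks)), path)
  invisible(path)
}

#' @export
print.fat_spectrum <- function(x, ...) {
  cat("fat_spectrum with", length(x$shift_ppm), "peak(s)\n")
  print(data.frame(shift_ppm = x$shift_ppm, amplitude = x$amplitude),
        row.names = FALSE)
  invisible(x)
}
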