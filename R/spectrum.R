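#' Construct a sampled spectrum
#'
#' A spectrum is a function of wavelength sampled on a strictly increasing
#' grid.  It is the common container for absorption coefficients
#' (\eqn{\mu_a(\lambda)}, mm\eqn{^{-1}}), conversion rates and conversion
#' CDFs (dimensionless probabilities), and detected photon-count spectra.
#'
#' @param wavelength_nm numeric, strictly increasing wavelengths in nm.
#' @param value numeric, nonnegative values, same length as `wavelength_nm`.
#' @return An object of class `mc_spectrum`: a list with elements
#'   `wavelength_nm` and `value`.
#' @examples
#' s <- mc_spectrum(c(810, 870, 932), c(0.1, 0.2, 0.15))
#' interp_spectrum(s, 840)
#' @export
mc_spectrum <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  s <- structure(list(wavelength_nm = wavelength_nm, value = value),
                 class = "mc_spectrum")
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  stopifnot(inherits(s, "mc_spectrum"))
  w <- s$wavelength_nm; v <- s$value
  if (length(w) < 1L || length(w) != length(v))
    stop("spectrum: wavelength and value must have equal length >= 1")
  if (anyNA(w) || anyNA(v))
    stop("spectrum: NA not allowed")
  if (length(w) > 1L && any(diff(w) <= 0))
    stop("spectrum: wavelengths must be strictly increasing")
  if (any(v < 0))
    stop("spectrum: values must be nonnegative")
  invisible(s)
}

#' @export
print.mc_spectrum <- function(x, ...) {
  cat(sprintf("<mc_spectrum> %d points, %.6g-%.6g nm, values [%.4g, %.4g]\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$value), max(x$value)))
  invisible(x)
}

#' Interpolate a spectrum at arbitrary wavelengths
#'
#' Linear interpolation between bracketing grid points.  Queries outside the
#' grid clamp to the end values (no extrapolation): all simulated wavelength
#' shifts stay inside the declared emission band by construction, so clamping
#' only ever affects degenerate configuration queries.
#'
#' @param s an [mc_spectrum()].
#' @param lam_nm numeric vector of query wavelengths (nm).
#' @return numeric vector of interpolated values.
#' @export
interp_spectrum <- function(s, lam_nm) {
  validate_spectrum(s)
  if (length(s$wavelength_nm) == 1L)
    return(rep(s$value, length(lam_nm)))
  stats::approx(s$wavelength_nm, s$value, xout = lam_nm, rule = 2)$y
}

#' Read / write a spectrum as two-column CSV
#'
#' The on-disk format is CSV with a required header and columns
#' `wavelength_nm` and `value`.
#'
#' @param path file path.
#' @return `read_spectrum_csv` returns an [mc_spectrum()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("spectrum CSV must have header columns 'wavelength_nm' and 'value': ", path)
  mc_spectrum(d$wavelength_nm, d$value)
}

#' @param s an [mc_spectrum()] to write.
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(s, path) {
  validate_spectrum(s)
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelength_nm, value = s$value),
    path, row.names = FALSE)
  invisible(path)
}

#' Build a conversion CDF from a rate spectrum
#'
#' Fluorescence and Raman conversion rates are proportional to the material's
#' re-emission spectra; the per-event decision compares one uniform variate
#' against the cumulative conversion probability indexed by wavelength.  The
#' CDF is built by discrete summation over the emission grid (the grid is a
#' set of discrete emission lines, not a density), so the cumulative mass at
#' grid point i is `scale * sum(rate[1..i])`.
#'
#' @param rate an [mc_spectrum()] of nonnegative conversion rates.
#' @param scale nonnegative proportionality constant applied to the rates.
#' @return An [mc_spectrum()] holding the nondecreasing CDF; its final value
#'   is the total per-event conversion probability.
#' @examples
#' r <- mc_spectrum(1:4, rep(1, 4))
#' build_conversion_cdf(r, 2.5e-4)$value  # 0.25, 0.5, 0.75, 1.0 (x 1e-3)
#' @export
build_conversion_cdf <- function(rate, scale) {
  validate_spectrum(rate)
  if (!is.numeric(scale) || length(scale) != 1L || scale < 0)
    stop("scale must be a single nonnegative number")
  cdf <- cumsum(scale * rate$value)
  tot <- cdf[length(cdf)]
  if (tot > 1 + 1e-12)
    stop(sprintf("total conversion probability %.6g exceeds 1; reduce scale", tot))
  mc_spectrum(rate$wavelength_nm, pmin(cdf, 1))
}
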