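#' Empirical dispersion model for tissue-like media
#'
#' In the near-infrared window the scattering coefficient of tissue follows a
#' decreasing power law while the anisotropy factor and refractive index are
#' nearly linear in wavelength:
#' \deqn{\mu_s(\lambda) = a_1\,\lambda^{-a_2},\quad
#'       g(\lambda) = a_3 + a_4\lambda,\quad
#'       n(\lambda) = a_5 + a_6\lambda.}
#' A material's wavelength-dependent optical properties are therefore carried
#' by just six coefficients (plus tabulated \eqn{\mu_a}, fluorescence and
#' Raman spectra, which have no useful empirical form).
#'
#' @param a1 scattering amplitude, mm^-1 nm^a2; must be > 0.
#' @param a2 scattering power, dimensionless; must be >= 0.
#' @param a3,a4 anisotropy intercept (dimensionless) and slope (nm^-1).
#' @param a5,a6 refractive-index intercept (dimensionless) and slope (nm^-1).
#' @return An object of class `mc_dispersion`.
#' @examples
#' d <- mc_dispersion(a1 = 2.4e6, a2 = 2, a3 = 0.9, a4 = 0, a5 = 1.4, a6 = 0)
#' mu_s_at(d, 800)  # 3.75 mm^-1
#' @export
mc_dispersion <- function(a1, a2, a3 = 0.9, a4 = 0, a5 = 1.4, a6 = 0) {
  if (!(is.finite(a1) && a1 > 0)) stop("a1 must be a positive real number")
  if (!(is.finite(a2) && a2 >= 0)) stop("a2 must be a nonnegative real number")
  structure(list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6),
            class = "mc_dispersion")
}

#' @export
print.mc_dispersion <- function(x, ...) {
  cat(sprintf(
    "<mc_dispersion> mu_s = %.4g * lam^-%.4g, g = %.4g + %.3g*lam, n = %.4g + %.3g*lam\n",
    x$a1, x$a2, x$a3, x$a4, x$a5, x$a6))
  invisible(x)
}

#' Evaluate dispersion laws at a wavelength
#'
#' @param model an [mc_dispersion()].
#' @param lam_nm wavelength(s) in nm; must be > 0 for `mu_s_at`.
#' @return `mu_s_at`: scattering coefficient in mm^-1; `g_at`: anisotropy
#'   factor; `n_at`: refractive index.
#' @export
mu_s_at <- function(model, lam_nm) {
  stopifnot(inherits(model, "mc_dispersion"))
  if (any(lam_nm <= 0)) stop("wavelength must be positive")
  model$a1 * lam_nm^(-model$a2)
}

#' @rdname mu_s_at
#' @export
g_at <- function(model, lam_nm) {
  stopifnot(inherits(model, "mc_dispersion"))
  model$a3 + model$a4 * lam_nm
}

#' @rdname mu_s_at
#' @export
n_at <- function(model, lam_nm) {
  stopifnot(inherits(model, "mc_dispersion"))
  model$a5 + model$a6 * lam_nm
}

#' Check a dispersion model over an operating band
#'
#' Validates that 0 <= g < 1 and n >= 1 for every wavelength of the band;
#' violations are configuration errors raised at material load time.
#'
#' @param model an [mc_dispersion()].
#' @param band_nm numeric vector of wavelengths to check (nm).
#' @return `model`, invisibly.
#' @export
validate_dispersion <- function(model, band_nm) {
  g <- g_at(model, band_nm)
  n <- n_at(model, band_nm)
  if (any(g < 0) || any(g >= 1))
    stop("dispersion model yields anisotropy outside [0, 1) over the operating band")
  if (any(n < 1))
    stop("dispersion model yields refractive index < 1 over the operating band")
  invisible(model)
}
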