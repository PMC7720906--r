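#' Per-event random-variable samplers
#'
#' All Monte Carlo decisions in the transport engine reduce to seven kinds of
#' draws, each a pure function mapping a uniform(0,1) variate to a physical
#' quantity.  Keeping them pure (no hidden RNG state) lets the compiled
#' engine be replayed against this reference implementation on a recorded
#' variate stream.
#'
#' Note on the step-length CDF: the sampler uses the standard exponential
#' free-path law \eqn{F(l) = 1 - e^{-\mu_s l}} with inverse
#' \eqn{l = -\ln(1-\xi)/\mu_s}.  (A variant with an extra \eqn{\mu_s} factor
#' inside the exponential-law CDF sometimes appears in print but is not a
#' distribution function; the Russian-roulette absorption rule below uses the
#' same standard form, which keeps the two mechanisms consistent.)
#'
#' @param xi uniform(0,1) variate(s).
#' @param mu_s scattering coefficient, mm^-1 (> 0).
#' @return `sample_step_length`: free path in mm.
#' @name samplers
NULL

#' @rdname samplers
#' @export
sample_step_length <- function(xi, mu_s) {
  if (any(mu_s <= 0))
    stop("mu_s must be > 0 (vacuum gaps are handled by the geometry, not the sampler)")
  stopifnot(all(xi >= 0), all(xi < 1))
  -log(1 - xi) / mu_s
}

#' @rdname samplers
#' @export
sample_azimuth <- function(xi) {
  stopifnot(all(xi >= 0), all(xi < 1))
  2 * pi * xi
}

#' Sample the Henyey-Greenstein polar deflection angle
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function with
#' anisotropy `g` (mean cosine of the deflection).  For |g| below 1e-6 the
#' closed form is singular and the isotropic limit cos(theta) = 2 xi - 1 is
#' used.
#'
#' @param xi uniform(0,1) variate(s).
#' @param g anisotropy factor, |g| < 1.
#' @return polar angle theta in radians, in [0, pi].
#' @export
sample_polar_hg <- function(xi, g) {
  stopifnot(all(xi >= 0), all(xi <= 1))
  if (abs(g) >= 1) stop("|g| must be < 1")
  if (abs(g) < 1e-6) {
    ct <- 2 * xi - 1
  } else {
    f <- (1 - g^2) / (1 - g + 2 * g * xi)
    ct <- (1 + g^2 - f^2) / (2 * g)
  }
  acos(pmin(1, pmax(-1, ct)))
}

#' Russian-roulette absorption test
#'
#' The photon is an indivisible particle (no packet weight): after traveling
#' a segment of length `l` in a medium with absorption `mu_a`, it is absorbed
#' iff `xi < 1 - exp(-mu_a * l)`, i.e. with the Beer-Lambert absorption
#' probability over the traveled segment.
#'
#' @param xi uniform(0,1) variate(s).
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param l traveled segment length, mm (>= 0).
#' @return logical: `TRUE` = absorbed, `FALSE` = survives.
#' @export
absorption_occurs <- function(xi, mu_a, l) {
  stopifnot(all(mu_a >= 0), all(l >= 0))
  xi < 1 - exp(-mu_a * l)
}

#' Sample a wavelength shift from a conversion CDF
#'
#' Compares one uniform variate against the cumulative conversion
#' probabilities of every emission wavelength; the chosen wavelength is the
#' shortest one whose CDF value exceeds the variate (inverse-CDF sampling on
#' the discrete grid).  If the variate exceeds the total conversion
#' probability the event does not occur.
#'
#' @param xi a single uniform(0,1) variate.
#' @param cdf numeric nondecreasing CDF values over the emission grid (or an
#'   [mc_spectrum()] holding them); final value <= 1.
#' @return 1-based grid index of the selected wavelength, or `NA_integer_`
#'   for "no shift" (elastic propagation).
#' @export
sample_shift_wavelength <- function(xi, cdf) {
  if (inherits(cdf, "mc_spectrum")) cdf <- cdf$value
  n <- length(cdf)
  if (n == 0L || xi >= cdf[n]) return(NA_integer_)
  which.max(cdf > xi)  # first index with cdf > xi
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized reflectances for light hitting the
#' interface from medium `n1` into `n2` at incidence angle `theta1`:
#' \deqn{R = \frac12\left[\left(\frac{n_1\cos\theta_1 - n_2\cos\theta_2}
#'  {n_1\cos\theta_1 + n_2\cos\theta_2}\right)^2 +
#'  \left(\frac{n_1\cos\theta_2 - n_2\cos\theta_1}
#'  {n_1\cos\theta_2 + n_2\cos\theta_1}\right)^2\right]}
#' with `theta2` from Snell's law; beyond the critical angle R = 1 (total
#' internal reflection).
#'
#' @param n1,n2 refractive indices (>= 1).
#' @param theta1 incidence angle in radians, in [0, pi/2].
#' @return reflectance in [0, 1].
#' @export
fresnel_reflectance <- function(n1, n2, theta1) {
  stopifnot(n1 >= 1, n2 >= 1, theta1 >= 0, theta1 <= pi / 2 + 1e-12)
  s1 <- sin(theta1)
  s2 <- n1 * s1 / n2
  if (s2 >= 1) return(1)
  c1 <- cos(theta1)
  c2 <- sqrt(1 - s2 * s2)
  rs <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
  rp <- (n1 * c2 - n2 * c1) / (n1 * c2 + n2 * c1)
  0.5 * (rs * rs + rp * rp)
}

#' @rdname samplers
#' @param R reflectance in [0, 1].
#' @return `reflect_or_transmit`: `"REFLECT"` iff `xi < R`, else `"TRANSMIT"`.
#' @export
reflect_or_transmit <- function(xi, R) {
  stopifnot(R >= 0, R <= 1)
  if (xi < R) "REFLECT" else "TRANSMIT"
}

#' Rotate a unit direction by sampled scattering angles
#'
#' Deflects direction `u` by polar angle `theta` (about `u`) with azimuth
#' `phi` in the local frame, using the standard local-frame rotation with the
#' |u_z| ~ 1 special case.
#'
#' @param u unit 3-vector.
#' @param theta polar deflection angle (rad).
#' @param phi azimuth (rad).
#' @return unit 3-vector.
#' @export
rotate_direction <- function(u, theta, phi) {
  if (abs(sum(u * u) - 1) > 1e-9) stop("direction must be a unit vector")
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi);   sp <- sin(phi)
  if (abs(u[3]) > 1 - 1e-12) {
    v <- c(st * cp, st * sp, ct * sign(u[3]))
  } else {
    den <- sqrt(1 - u[3]^2)
    v <- c(st * (u[1] * u[3] * cp - u[2] * sp) / den + u[1] * ct,
           st * (u[2] * u[3] * cp + u[1] * sp) / den + u[2] * ct,
           -st * cp * den + u[3] * ct)
  }
  v / sqrt(sum(v * v))
}
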