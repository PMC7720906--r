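#' Emission wavelength grid
#'
#' The discrete set of wavelengths a photon can occupy.  Grid point 1 is the
#' source (excitation) wavelength; points 2..(n+1) are the re-emission
#' wavelengths, equally spaced over `[lo_nm, hi_nm]`.  Keeping the source
#' wavelength on the grid allows the fluorescence branch that re-emits at the
#' initial wavelength.
#'
#' @param n number of re-emission wavelengths (default 100).
#' @param lo_nm,hi_nm re-emission band edges in nm (defaults 810, 932).
#' @param source_nm excitation wavelength in nm (default 785).
#' @return An object of class `mc_grid`: list with `wavelength_nm`
#'   (length n + 1) and `source_index` (always 1).
#' @export
emission_grid <- function(n = 100, lo_nm = 810, hi_nm = 932, source_nm = 785) {
  stopifnot(n >= 1, lo_nm < hi_nm, source_nm < lo_nm)
  structure(list(
    wavelength_nm = c(source_nm, seq(lo_nm, hi_nm, length.out = n)),
    source_index = 1L), class = "mc_grid")
}

#' @export
print.mc_grid <- function(x, ...) {
  w <- x$wavelength_nm
  cat(sprintf("<mc_grid> source %.6g nm + %d emission points %.6g-%.6g nm\n",
              w[1], length(w) - 1L, w[2], w[length(w)]))
  invisible(x)
}

#' Define a material
#'
#' A material couples an integer label (used by geometries) to its optical
#' properties: elastic scattering, anisotropy and refractive index through a
#' dispersion model (or direct tabulated spectra), a tabulated absorption
#' spectrum, and the fluorescence / Raman conversion CDFs.  The CDFs are
#' cumulative per-event conversion probabilities indexed by emission
#' wavelength; their final values are the total probabilities that an
#' absorption event re-emits (fluorescence) or that a propagation step
#' Raman-shifts.
#'
#' @param id positive integer label (0 is reserved for void).
#' @param dispersion an [mc_dispersion()], or `NULL` if tabulated overrides
#'   are supplied.
#' @param mu_a an [mc_spectrum()] of absorption coefficients (mm^-1), or a
#'   single number for a flat spectrum.
#' @param rho_F,rho_R [mc_spectrum()] conversion CDFs on the emission grid
#'   (see [build_conversion_cdf()]), or `NULL` for "event disabled".
#' @param mu_s,g,n optional tabulated [mc_spectrum()] overrides (or single
#'   numbers); when given they take precedence over `dispersion`.
#' @param name optional human-readable name.
#' @return An object of class `mc_material`.
#' @export
mc_material <- function(id, dispersion = NULL, mu_a = 0,
                        rho_F = NULL, rho_R = NULL,
                        mu_s = NULL, g = NULL, n = NULL, name = NULL) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L) stop("material id must be a positive integer")
  as_spec <- function(x) {
    if (is.null(x) || inherits(x, "mc_spectrum")) return(x)
    if (is.numeric(x) && length(x) == 1L) return(mc_spectrum(1, x))
    stop("expected an mc_spectrum or a single number")
  }
  m <- structure(list(
    id = id, name = if (is.null(name)) paste0("material_", id) else name,
    dispersion = dispersion,
    mu_a = as_spec(mu_a), rho_F = as_spec(rho_F), rho_R = as_spec(rho_R),
    mu_s = as_spec(mu_s), g = as_spec(g), n = as_spec(n)),
    class = "mc_material")
  validate_material(m)
  m
}

validate_material <- function(m) {
  stopifnot(inherits(m, "mc_material"))
  if (is.null(m$dispersion) && is.null(m$mu_s))
    stop("material needs either a dispersion model or a tabulated mu_s")
  if (!is.null(m$dispersion)) stopifnot(inherits(m$dispersion, "mc_dispersion"))
  for (f in c("rho_F", "rho_R")) {
    s <- m[[f]]
    if (is.null(s)) next
    if (any(diff(s$value) < -1e-15))
      stop(f, " CDF must be nondecreasing along wavelength")
    if (s$value[length(s$value)] > 1 + 1e-12)
      stop(f, " CDF final value exceeds 1")
  }
  invisible(m)
}

#' @export
print.mc_material <- function(x, ...) {
  tot <- function(s) if (is.null(s)) 0 else s$value[length(s$value)]
  cat(sprintf("<mc_material> id=%d '%s'  P(fluor)=%.3g  P(Raman)=%.3g\n",
              x$id, x$name, tot(x$rho_F), tot(x$rho_R)))
  invisible(x)
}

# Tabulate per-material optical properties on the emission grid.
# Returns matrices [n_grid x n_materials] (column j = material with id j):
# mu_s, mu_a, g, n, plus cdf_R and cdf_F ([n_grid x n_materials]).
# Missing ids (holes in the id sequence) are an error: geometries address
# materials by id.
material_table <- function(materials, grid) {
  stopifnot(inherits(grid, "mc_grid"))
  if (inherits(materials, "mc_material")) materials <- list(materials)
  ids <- vapply(materials, function(m) m$id, integer(1))
  nmat <- max(ids)
  if (anyDuplicated(ids)) stop("duplicate material ids")
  if (!setequal(ids, seq_len(nmat)))
    stop("material ids must be 1..n without holes")
  w <- grid$wavelength_nm
  K <- length(w)
  tab <- function(fill) matrix(fill, nrow = K, ncol = nmat)
  out <- list(mu_s = tab(0), mu_a = tab(0), g = tab(0), n = tab(1),
              cdf_R = tab(0), cdf_F = tab(0), ids = seq_len(nmat),
              names = character(nmat), grid = grid)
  for (m in materials) {
    j <- m$id
    out$names[j] <- m$name
    if (!is.null(m$mu_s)) {
      out$mu_s[, j] <- interp_spectrum(m$mu_s, w)
      out$g[, j]    <- if (!is.null(m$g)) interp_spectrum(m$g, w) else 0
      out$n[, j]    <- if (!is.null(m$n)) interp_spectrum(m$n, w) else 1.4
    } else {
      validate_dispersion(m$dispersion, w)
      out$mu_s[, j] <- mu_s_at(m$dispersion, w)
      out$g[, j]    <- g_at(m$dispersion, w)
      out$n[, j]    <- n_at(m$dispersion, w)
    }
    out$mu_a[, j] <- interp_spectrum(m$mu_a, w)
    if (!is.null(m$rho_R)) out$cdf_R[, j] <- cdf_on_grid(m$rho_R, grid)
    if (!is.null(m$rho_F)) out$cdf_F[, j] <- cdf_on_grid(m$rho_F, grid)
  }
  if (any(out$mu_s <= 0)) stop("mu_s must be positive over the whole grid")
  if (any(out$g < 0 | out$g >= 1)) stop("g out of [0,1) over the grid")
  if (any(out$n < 1)) stop("n < 1 over the grid")
  out
}

# Align a conversion CDF with the engine grid.  The CDF must be defined on a
# subset of the grid wavelengths (within 1e-9 nm); grid points before the
# CDF's first point get 0, points after its last keep the total.
cdf_on_grid <- function(cdf, grid) {
  w <- grid$wavelength_nm
  idx <- match(round(cdf$wavelength_nm, 9), round(w, 9))
  if (anyNA(idx))
    stop("conversion CDF wavelengths must coincide with emission grid points")
  out <- numeric(length(w))
  out[idx] <- cdf$value
  # carry forward between listed points; zero before the first
  for (i in seq_along(out)[-1])
    if (!(i %in% idx)) out[i] <- out[i - 1]
  if (any(diff(out) < -1e-15)) stop("conversion CDF must be nondecreasing")
  out
}
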