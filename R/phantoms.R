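#' In-silico tissue-phantom fixtures
#'
#' Generators for fully synthetic replicas of the validation phantoms and
#' the depth-study media, so every simulation in the package runs from
#' generated inputs.  Phantoms I and II are 10-mm single layers of PDMS-like
#' and nylon-like material; phantom III is a 913-um PDMS-like layer over a
#' 10-mm nylon-like substrate.  Optical properties are smooth synthetic
#' curves pinned to the measured endpoint values over 500-1000 nm (PDMS:
#' mu_a 0.11 -> 0.075 mm^-1 linear, mu_s' 0.65 -> 0.45 mm^-1 power law;
#' nylon: mu_a 0.02 -> 0.01 mm^-1, mu_s' 1.05 -> 0.25 mm^-1), with g = 0.9
#' and n = 1.4.  They are stand-ins for the measured dispersion curves, not
#' digitizations.
#'
#' @param which phantom name: "I", "II" or "III".
#' @param representation "layered" (exact plane boundaries, default) or
#'   "voxel" (rasterized label volume).
#' @param dims voxel counts for `representation = "voxel"`; defaults to
#'   256^3 for I/II and 501 x 501 x 203 for III.
#' @param rho_R_total,rho_F_total total per-event conversion probabilities
#'   assigned to the synthetic Raman and fluorescence spectra.  The true
#'   proportionality constants linking spectra to conversion rates are
#'   unknown; these are documented fixture values with no claim of physical
#'   absoluteness.
#' @param n_peaks synthetic Raman peaks per material.
#' @param seed seed for the synthetic spectra.
#' @param half_mm lateral half-extent of the layered representation (mm).
#' @return A list of class `mc_phantom`: `geometry`, `materials`, `grid`,
#'   `source`, `detector`, `name`.
#' @export
make_phantom <- function(which = c("I", "II", "III"),
                         representation = c("layered", "voxel"), dims = NULL,
                         rho_R_total = 1e-3, rho_F_total = 0.1, n_peaks = 4,
                         seed = 20201027, half_mm = 10) {
  which <- match.arg(which)
  representation <- match.arg(representation)
  grid <- emission_grid()
  pdms <- phantom_material(1L, "PDMS_like", mu_a_ends = c(0.11, 0.075),
                           mu_sp_ends = c(0.65, 0.45), grid = grid,
                           rho_R_total = rho_R_total,
                           rho_F_total = rho_F_total, n_peaks = n_peaks,
                           seed = seed)
  nylon <- phantom_material(2L, "nylon_like", mu_a_ends = c(0.02, 0.01),
                            mu_sp_ends = c(1.05, 0.25), grid = grid,
                            rho_R_total = rho_R_total,
                            rho_F_total = rho_F_total, n_peaks = n_peaks,
                            seed = seed)
  if (which == "I") {
    geom <- layered_geometry(c(0, 10), 1L, half_mm)
    mats <- list(pdms)
  } else if (which == "II") {
    nylon$id <- 1L
    geom <- layered_geometry(c(0, 10), 1L, half_mm)
    mats <- list(nylon)
  } else {
    geom <- layered_geometry(c(0, 0.913, 10.913), c(1L, 2L), half_mm)
    mats <- list(pdms, nylon)
  }
  if (representation == "voxel") {
    if (is.null(dims)) dims <- if (which == "III") c(501, 501, 203)
                                else c(256, 256, 256)
    geom <- rasterize_layered(geom, dims)
  }
  structure(list(geometry = geom, materials = mats, grid = grid,
                 source = source_spec(), detector = detector_spec(),
                 name = paste0("phantom_", which)), class = "mc_phantom")
}

#' @export
print.mc_phantom <- function(x, ...) {
  cat(sprintf("<mc_phantom> %s: %d material(s)\n", x$name,
              length(x$materials)))
  print(x$geometry)
  invisible(x)
}

# one phantom material with dispersion pinned to the printed endpoints
phantom_material <- function(id, profile, mu_a_ends, mu_sp_ends, grid,
                             rho_R_total, rho_F_total, n_peaks, seed) {
  # power law through (500 nm, mu_sp_ends[1]) and (1000 nm, mu_sp_ends[2]);
  # mu_s = mu_s' / (1 - g) with g = 0.9
  a2 <- log(mu_sp_ends[1] / mu_sp_ends[2]) / log(1000 / 500)
  a1 <- (mu_sp_ends[1] / 0.1) * 500^a2
  disp <- mc_dispersion(a1 = a1, a2 = a2, a3 = 0.9, a4 = 0, a5 = 1.4, a6 = 0)
  mu_a <- mc_spectrum(c(500, 1000), mu_a_ends)
  sp <- make_material_spectra(profile, n_peaks = n_peaks, seed = seed,
                              grid = grid)
  rho_R <- if (rho_R_total > 0)
    build_conversion_cdf(sp$raman_rate, rho_R_total / sum(sp$raman_rate$value))
  rho_F <- if (rho_F_total > 0)
    build_conversion_cdf(sp$fluor_rate, rho_F_total / sum(sp$fluor_rate$value))
  mc_material(id, dispersion = disp, mu_a = mu_a, rho_F = rho_F,
              rho_R = rho_R, name = profile)
}

#' Synthetic Raman and fluorescence rate spectra
#'
#' Stand-ins for measured material spectra: the Raman rate is a sum of
#' narrow Lorentzian peaks at profile-specific positions on the re-emission
#' grid and the fluorescence rate is one broad smooth hump.  The two
#' profiles draw their peaks from interleaved position slots at least 3 bins
#' apart, so peaks in a layered simulation can be attributed unambiguously
#' to a layer.
#'
#' @param profile "PDMS_like" or "nylon_like".
#' @param n_peaks number of Raman peaks (>= 1).
#' @param seed deterministic seed for slot choice and peak amplitudes.
#' @param grid an [emission_grid()].
#' @return list with `raman_rate` and `fluor_rate` ([mc_spectrum()]s on the
#'   re-emission grid, unnormalized) and `peak_bins` (1-based re-emission
#'   bin indices of the Raman peaks).
#' @export
make_material_spectra <- function(profile = c("PDMS_like", "nylon_like"),
                                  n_peaks = 4, seed = 20201027,
                                  grid = emission_grid()) {
  profile <- match.arg(profile)
  stopifnot(n_peaks >= 1)
  w <- grid$wavelength_nm[-grid$source_index]
  nb <- length(w)
  # interleaved slots 7 bins apart; PDMS takes odd slots, nylon even
  slots <- seq(5L, nb - 4L, by = 7L)
  mine <- slots[seq_along(slots) %% 2L == (profile == "PDMS_like")]
  if (n_peaks > length(mine))
    stop("too many peaks for disjoint placement: max ", length(mine))
  rs <- local_rng(seed + (profile == "nylon_like"))
  peak_bins <- sort(mine[order(rs(length(mine)))][seq_len(n_peaks)])
  amp <- 0.5 + 0.5 * rs(n_peaks)
  gamma <- 1.2  # Lorentzian half-width in bins
  bins <- seq_len(nb)
  raman <- numeric(nb)
  for (i in seq_len(n_peaks))
    raman <- raman + amp[i] * gamma^2 / ((bins - peak_bins[i])^2 + gamma^2)
  center <- if (profile == "PDMS_like") 0.35 * nb else 0.6 * nb
  fluor <- exp(-0.5 * ((bins - center) / (0.25 * nb))^2)
  list(raman_rate = mc_spectrum(w, raman),
       fluor_rate = mc_spectrum(w, fluor),
       peak_bins = peak_bins)
}

# tiny deterministic uniform generator (keeps R's global RNG untouched)
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

#' Depth-study medium: homogeneous semi-infinite slab
#'
#' The semi-infinite phantom of the sensing-depth analysis, approximated as
#' a 2 x 2 x 2 cm slab: homogeneous, g = 0.9, n = 1.4,
#' mu_s = mu_s' / (1 - g), a flat Raman conversion-rate spectrum over the
#' re-emission band, and fluorescence disabled (the depth study concerns
#' Raman statistics only).  Source: 785-nm Gaussian point source (std
#' 0.1 um, 8-degree cone); detector: the annular fiber probe.
#'
#' `rho_R` is the *per-wavelength* conversion rate: the flat rate assigned
#' to each of the 100 re-emission wavelengths, so the total per-collision
#' conversion probability (the final CDF value) is `100 * rho_R`.  This is
#' the only reading under which the conversion rate influences the sensing
#' depth over the studied range 1e-6..1e-3 (per-collision totals
#' 1e-4..0.1): were the quoted numbers the CDF totals, the first-shift
#' depletion over typical detected path lengths (tens to hundreds of
#' collisions) would be negligible at every studied rate and the
#' depth-vs-rate dependence would vanish.
#'
#' @param mu_a_mm absorption coefficient (mm^-1, >= 0).
#' @param mu_s_prime_mm reduced scattering coefficient (mm^-1, > 0).
#' @param rho_R per-wavelength Raman conversion rate (dimensionless);
#'   total per-collision conversion probability is `100 * rho_R` and must
#'   be <= 1.
#' @param g,n anisotropy and refractive index.
#' @param representation "layered" (exact planes, default) or "voxel"
#'   (256^3 rasterization of the same slab).
#' @param dims voxel counts when `representation = "voxel"`.
#' @param size_mm slab edge length (mm).
#' @return A list of class `mc_phantom`, with the extra element
#'   `rho_step_total` (the per-collision conversion probability).
#' @export
make_depth_medium <- function(mu_a_mm, mu_s_prime_mm, rho_R,
                              g = 0.9, n = 1.4,
                              representation = c("layered", "voxel"),
                              dims = c(256, 256, 256), size_mm = 20) {
  representation <- match.arg(representation)
  grid <- emission_grid()
  w <- grid$wavelength_nm[-grid$source_index]
  total <- length(w) * rho_R
  stopifnot(mu_a_mm >= 0, mu_s_prime_mm > 0, rho_R >= 0, total <= 1)
  cdf <- if (total > 0)
    build_conversion_cdf(mc_spectrum(w, rep(1, length(w))), rho_R)
  mat <- mc_material(1L, mu_s = mu_s_prime_mm / (1 - g), g = g, n = n,
                     mu_a = mu_a_mm, rho_R = cdf, rho_F = NULL,
                     name = sprintf("slab_mua%g_musp%g", mu_a_mm,
                                    mu_s_prime_mm))
  geom <- layered_geometry(c(0, size_mm), 1L, size_mm / 2)
  if (representation == "voxel") geom <- rasterize_layered(geom, dims)
  structure(list(geometry = geom, materials = list(mat), grid = grid,
                 source = source_spec(), detector = detector_spec(),
                 rho_step_total = total,
                 name = "depth_medium"), class = "mc_phantom")
}
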