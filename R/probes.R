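#' Fiber-probe detector specification
#'
#' The handheld-probe collection geometry: an annular aperture on the top
#' surface (z = 0) between `inner_mm` and `outer_mm` radial distance from
#' the probe axis, collecting photons whose exit direction lies within
#' `accept_deg` of the outward surface normal.  The defaults model a 600-um
#' diameter collection cylinder surrounding a 400-um diameter illumination
#' disk with a 30-degree acceptance half-angle; setting `inner_mm = 0` gives
#' the alternative full-disk reading of the same probe.
#'
#' Acceptance is evaluated in void, after refraction at the exit surface,
#' since detection physically happens outside the medium.
#'
#' @param inner_mm,outer_mm annulus radii (mm), `0 <= inner < outer`.
#' @param accept_deg acceptance half-angle in degrees, in (0, 90].
#' @param center_mm lateral (x, y) center of the probe axis.
#' @param z_tol_mm tolerance for "exited through the top surface" (mm).
#' @return An object of class `mc_detector`.
#' @export
detector_spec <- function(inner_mm = 0.2, outer_mm = 0.3, accept_deg = 30,
                          center_mm = c(0, 0), z_tol_mm = 1e-3) {
  stopifnot(inner_mm >= 0, outer_mm > inner_mm, accept_deg > 0,
            accept_deg <= 90)
  structure(list(inner_mm = inner_mm, outer_mm = outer_mm,
                 accept_deg = accept_deg, cx_mm = center_mm[1],
                 cy_mm = center_mm[2], z_tol_mm = z_tol_mm),
            class = "mc_detector")
}

#' @export
print.mc_detector <- function(x, ...) {
  cat(sprintf("<mc_detector> annulus [%g, %g) mm, acceptance %g deg\n",
              x$inner_mm, x$outer_mm, x$accept_deg))
  invisible(x)
}

#' Classify escaped photons against the detector aperture
#'
#' A record is accepted iff it escaped through the top surface, its exit
#' point lies in the annulus `[inner, outer)` around the probe axis, and the
#' angle between its exit direction and the outward surface normal is at
#' most the acceptance half-angle.
#'
#' @param records data.frame of photon records (from [run_simulation()]).
#' @param det a [detector_spec()].
#' @return logical vector, one element per record.
#' @export
accept <- function(records, det) {
  stopifnot(inherits(det, "mc_detector"))
  r <- sqrt((records$x - det$cx_mm)^2 + (records$y - det$cy_mm)^2)
  cosang <- -records$uz  # outward normal is -z
  records$status == 2 &
    abs(records$z) <= det$z_tol_mm &
    records$uz < 0 &
    r >= det$inner_mm & r < det$outer_mm &
    cosang >= cos(det$accept_deg * pi / 180)
}

#' Bin accepted photons into a detected spectrum
#'
#' Counts accepted records per final-wavelength grid point over the
#' re-emission band; photons that exit still at the source wavelength are
#' tallied separately as the elastic channel.
#'
#' @param records data.frame of photon records.
#' @param det a [detector_spec()].
#' @param grid the [emission_grid()] used in the simulation.
#' @param launched total photons launched (for bookkeeping).
#' @return An object of class `mc_detected_spectrum`: list with
#'   `wavelength_nm` (re-emission grid), `counts`, `elastic_counts`,
#'   `launched`.
#' @export
bin_spectrum <- function(records, det, grid, launched = NA_real_) {
  stopifnot(inherits(grid, "mc_grid"))
  ok <- accept(records, det)
  wl <- records$wl_index[ok]
  K <- length(grid$wavelength_nm)
  if (length(wl) && (any(wl < 1) || any(wl > K) || any(wl != round(wl))))
    stop("record wavelength index off the emission grid")
  counts <- tabulate(wl, nbins = K)
  structure(list(wavelength_nm = grid$wavelength_nm[-grid$source_index],
                 counts = counts[-grid$source_index],
                 elastic_counts = counts[grid$source_index],
                 launched = launched),
            class = "mc_detected_spectrum")
}

#' @export
print.mc_detected_spectrum <- function(x, ...) {
  cat(sprintf("<mc_detected_spectrum> %d bins, %d shifted + %d elastic photons\n",
              length(x$counts), sum(x$counts), x$elastic_counts))
  invisible(x)
}

#' Write a detected spectrum as CSV
#'
#' @param spec an `mc_detected_spectrum`.
#' @param path output file.
#' @export
write_detected_csv <- function(spec, path) {
  utils::write.csv(data.frame(wavelength_nm = spec$wavelength_nm,
                              counts = spec$counts), path, row.names = FALSE)
  invisible(path)
}
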