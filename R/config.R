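#' Write and read run configurations (JSON + CSV spectra)
#'
#' The on-disk run format is a versioned JSON file plus two-column CSV
#' spectra.  Physical quantities carry unit-suffixed key names (`_mm`,
#' `_nm`, `_deg`).  Each material section holds the dispersion coefficients
#' `a1..a6` (or tabulated `mu_s_csv`/`g_csv`/`n_csv` overrides), a
#' `mu_a_csv`, and the conversion-rate spectra `rho_F_csv` / `rho_R_csv`
#' with their proportionality constants `rho_F_scale` / `rho_R_scale`; the
#' conversion CDFs are rebuilt with [build_conversion_cdf()] at load time.
#' Voxel geometries reference a directory of grayscale image slices plus
#' `pitch_mm` / `origin_mm`.
#'
#' @param config an [run_config()] (or an `mc_phantom` fixture, for which
#'   run parameters are added with defaults).
#' @param dir output directory (created if missing).
#' @param photons,batches,seed,max_iterations run parameters used when
#'   `config` is a fixture.
#' @return `write_run_config`: the path of the JSON file, invisibly;
#'   `read_run_config`: an `mc_config`.
#' @export
write_run_config <- function(config, dir, photons = 1e5, batches = 1,
                             seed = 1, max_iterations = 1e5) {
  if (inherits(config, "mc_phantom"))
    config <- run_config(config$geometry, config$materials,
                         grid = config$grid, source = config$source,
                         detector = config$detector, photons = photons,
                         batches = batches, seed = seed,
                         max_iterations = max_iterations)
  stopifnot(inherits(config, "mc_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- lapply(config$materials, function(m) {
    entry <- list(id = m$id, name = m$name)
    if (!is.null(m$dispersion)) entry <- c(entry, unclass(m$dispersion))
    save_spec <- function(s, what) {
      f <- sprintf("material_%d_%s.csv", m$id, what)
      write_spectrum_csv(s, file.path(dir, f))
      f
    }
    entry$mu_a_csv <- save_spec(m$mu_a, "mu_a")
    for (ov in c("mu_s", "g", "n"))
      if (!is.null(m[[ov]]))
        entry[[paste0(ov, "_csv")]] <- save_spec(m[[ov]], ov)
    # store conversion *rates* (first differences of the CDF), scale 1
    for (cv in c("rho_F", "rho_R")) {
      if (is.null(m[[cv]])) next
      rate <- mc_spectrum(m[[cv]]$wavelength_nm, diff(c(0, m[[cv]]$value)))
      entry[[paste0(cv, "_csv")]] <- save_spec(rate, cv)
      entry[[paste0(cv, "_scale")]] <- 1
    }
    entry
  })
  geom <- config$geometry
  gj <- if (geom$kind == "LAYERED") {
    list(kind = "LAYERED", boundaries_mm = geom$boundaries,
         material_ids = geom$ids, half_x_mm = geom$half_x,
         half_y_mm = geom$half_y)
  } else {
    list(kind = "VOXEL", labels_rds = NA, dims = geom$dims,
         pitch_mm = geom$pitch, origin_mm = geom$origin,
         labels_csv = "labels.csv")
  }
  if (geom$kind == "VOXEL") {
    gj$labels_rds <- NULL
    utils::write.csv(data.frame(label = as.integer(geom$labels)),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  doc <- list(
    schema_version = 1L,
    photons = config$photons, batches = config$batches, seed = config$seed,
    max_iterations = config$max_iterations,
    grid = list(n = length(config$grid$wavelength_nm) - 1L,
                lo_nm = config$grid$wavelength_nm[2],
                hi_nm = max(config$grid$wavelength_nm),
                source_nm = config$grid$wavelength_nm[1]),
    source = unclass(config$source),
    detector = unclass(config$detector),
    geometry = gj,
    materials = mats)
  path <- file.path(dir, "config.json")
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @param path path to a `config.json`.
#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported or missing config schema_version in ", path)
  dir <- dirname(path)
  grid <- emission_grid(doc$grid$n, doc$grid$lo_nm, doc$grid$hi_nm,
                        doc$grid$source_nm)
  src <- do.call(source_spec, c(
    doc$source[c("radius_mm", "std_mm", "cone_deg", "z0_mm")],
    list(center_mm = c(doc$source$cx_mm, doc$source$cy_mm),
         wavelength_nm = doc$source$wavelength_nm)))
  det <- detector_spec(doc$detector$inner_mm, doc$detector$outer_mm,
                       doc$detector$accept_deg,
                       c(doc$detector$cx_mm, doc$detector$cy_mm),
                       doc$detector$z_tol_mm)
  gj <- doc$geometry
  geom <- if (identical(gj$kind, "LAYERED")) {
    layered_geometry(gj$boundaries_mm, gj$material_ids, gj$half_x_mm,
                     gj$half_y_mm)
  } else {
    lab <- utils::read.csv(file.path(dir, gj$labels_csv))$label
    voxel_geometry(array(lab, gj$dims), gj$pitch_mm, gj$origin_mm)
  }
  mats <- if (is.data.frame(doc$materials))
    lapply(seq_len(nrow(doc$materials)), function(i)
      as.list(doc$materials[i, ])) else doc$materials
  materials <- lapply(mats, function(e) {
    rd <- function(f) read_spectrum_csv(file.path(dir, f))
    disp <- if (!is.null(e$a1) && !is.na(e$a1))
      mc_dispersion(e$a1, e$a2, e$a3, e$a4, e$a5, e$a6)
    cdf <- function(cv) {
      f <- e[[paste0(cv, "_csv")]]
      if (is.null(f) || is.na(f)) return(NULL)
      build_conversion_cdf(rd(f), e[[paste0(cv, "_scale")]])
    }
    ov <- function(o) {
      f <- e[[paste0(o, "_csv")]]
      if (is.null(f) || is.na(f)) NULL else rd(f)
    }
    mc_material(e$id, dispersion = disp, mu_a = rd(e$mu_a_csv),
                rho_F = cdf("rho_F"), rho_R = cdf("rho_R"),
                mu_s = ov("mu_s"), g = ov("g"), n = ov("n"), name = e$name)
  })
  run_config(geom, materials, grid = grid, source = src, detector = det,
             photons = doc$photons, batches = doc$batches, seed = doc$seed,
             max_iterations = doc$max_iterations)
}
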