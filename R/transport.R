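#' Source and detector specifications
#'
#' The source is a monochromatic Gaussian-profile beam: photons start in the
#' void just above the surface, radially offset by a 2-D Gaussian of standard
#' deviation `std_mm` truncated at `radius_mm` (no photon is emitted beyond
#' the source radius; `radius_mm = 0` disables truncation), with directions
#' uniform in solid angle within the illumination cone half-angle `cone_deg`
#' about +z.  Ten numbers fully describe it.
#'
#' @param radius_mm source radius (mm); emission boundary.
#' @param std_mm standard deviation of the Gaussian radial profile (mm).
#' @param cone_deg illumination cone half-angle (degrees).
#' @param center_mm lateral (x, y) position of the beam axis.
#' @param z0_mm launch height above the surface (mm).
#' @param wavelength_nm source wavelength (informational; the grid's source
#'   point defines it for the engine).
#' @return An object of class `mc_source`.
#' @export
source_spec <- function(radius_mm = 0.2, std_mm = 1e-4, cone_deg = 8,
                        center_mm = c(0, 0), z0_mm = 1e-4,
                        wavelength_nm = 785) {
  stopifnot(radius_mm >= 0, std_mm >= 0, cone_deg >= 0, cone_deg <= 90,
            z0_mm > 0)
  structure(list(radius_mm = radius_mm, std_mm = std_mm, cone_deg = cone_deg,
                 cx_mm = center_mm[1], cy_mm = center_mm[2], z0_mm = z0_mm,
                 wavelength_nm = wavelength_nm), class = "mc_source")
}

#' Assemble a simulation run configuration
#'
#' @param geometry an `mc_geometry`.
#' @param materials list of [mc_material()] (ids 1..n).
#' @param grid an [emission_grid()].
#' @param source an [source_spec()].
#' @param detector a [detector_spec()] (used for record filtering and
#'   spectra).
#' @param photons photons per batch (positive integer).
#' @param batches number of independent batches.
#' @param seed integer RNG seed; each batch uses an independent substream.
#' @param max_iterations per-photon event-loop cap.
#' @return An object of class `mc_config`.
#' @export
run_config <- function(geometry, materials, grid = emission_grid(),
                       source = source_spec(), detector = detector_spec(),
                       photons = 1e5, batches = 1, seed = 1,
                       max_iterations = 1e5) {
  stopifnot(inherits(geometry, "mc_geometry"), inherits(grid, "mc_grid"),
            inherits(source, "mc_source"))
  photons <- as.integer(photons); batches <- as.integer(batches)
  if (is.na(photons) || photons < 1) stop("photons must be a positive integer")
  if (is.na(batches) || batches < 1) stop("batches must be a positive integer")
  if (inherits(materials, "mc_material")) materials <- list(materials)
  tab <- material_table(materials, grid)  # validates ids/spectra coverage
  used <- if (geometry$kind == "LAYERED") unique(geometry$ids) else
    setdiff(unique(as.integer(geometry$labels)), 0L)
  if (length(setdiff(used, tab$ids)))
    stop("geometry references material ids with no registered material")
  structure(list(geometry = geometry, materials = materials, grid = grid,
                 source = source, detector = detector, photons = photons,
                 batches = batches, seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations), table = tab),
            class = "mc_config")
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf("<mc_config> %s photons x %d batch(es), seed %d, %d material(s)\n",
              format(x$photons, big.mark = ","), x$batches, x$seed,
              length(x$materials)))
  print(x$geometry)
  invisible(x)
}

engine_geom <- function(geom) {
  if (geom$kind == "LAYERED") {
    list(kind = "LAYERED", boundaries = geom$boundaries, ids = geom$ids,
         half_x = geom$half_x, half_y = geom$half_y)
  } else {
    list(kind = "VOXEL", labels = as.integer(geom$labels), dims = geom$dims,
         pitch = geom$pitch, origin = geom$origin)
  }
}

engine_detector <- function(det) {
  list(inner_mm = det$inner_mm, outer_mm = det$outer_mm,
       accept_deg = det$accept_deg, z_tol_mm = det$z_tol_mm,
       cx_mm = det$cx_mm, cy_mm = det$cy_mm)
}

#' Run a Monte Carlo simulation
#'
#' Launches `photons x batches` photons through the compiled event-loop
#' engine.  Each batch uses an independent, deterministically seeded RNG
#' substream, so results are reproducible for a given (seed, photons,
#' batches) regardless of how batches are interleaved.
#'
#' @param config an [run_config()].
#' @param keep `"accepted"` returns only records that pass the detector
#'   aperture (memory-safe for large runs); `"all"` returns every photon
#'   record.
#' @param trace_depths if `TRUE`, also return, for every kept photon, the
#'   depth of each of its Raman conversion opportunities (the z position at
#'   every material-step Raman check).  Used by the conditional-expectation
#'   sensing-depth estimator; see [raman_depth_sample()].
#' @param progress print per-batch progress lines.
#' @return A list of class `mc_result`: `records` (data.frame, one row per
#'   kept photon), `counts` (named vector: launched, absorbed, escaped,
#'   iteration_cap, kept), `depth_traces` (list, if requested) and `meta`
#'   (seed, batches, config hash, grid).
#' @export
run_simulation <- function(config, keep = c("accepted", "all"),
                           trace_depths = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  keep <- match.arg(keep)
  keep_mode <- if (keep == "accepted") 1L else 0L
  if (keep_mode == 1L && is.null(config$detector))
    stop("keep = 'accepted' requires a detector in the config")
  tab <- config$table
  mats <- list(mu_s = tab$mu_s, mu_a = tab$mu_a, g = tab$g, n = tab$n,
               cdf_R = tab$cdf_R, cdf_F = tab$cdf_F)
  geom <- engine_geom(config$geometry)
  det <- if (is.null(config$detector)) list() else
    engine_detector(config$detector)
  src <- config$source[c("radius_mm", "std_mm", "cone_deg", "z0_mm",
                         "cx_mm", "cy_mm")]
  recs <- vector("list", config$batches)
  trcs <- vector("list", config$batches)
  counts <- c(launched = 0, absorbed = 0, escaped = 0, iteration_cap = 0,
              kept = 0)
  for (b in seq_len(config$batches)) {
    out <- mc_batch_cpp(geom, mats, src, det, config$photons,
                        as.double(config$seed), b, config$max_iterations,
                        keep_mode, NULL, FALSE, trace_depths)
    m <- out$records
    df <- as.data.frame(m)
    df$batch <- rep(b, nrow(df))
    recs[[b]] <- df
    if (trace_depths) trcs[[b]] <- out$depth_traces
    counts <- counts + out$counts
    if (progress)
      message(sprintf("batch %d/%d: %d photons, %d kept", b, config$batches,
                      config$photons, nrow(m)))
  }
  records <- do.call(rbind, recs)
  if (counts[["iteration_cap"]] > 0)
    warning(sprintf("%d photon(s) hit the iteration cap",
                    as.integer(counts[["iteration_cap"]])))
  structure(list(records = records, counts = counts,
                 depth_traces = if (trace_depths) do.call(c, trcs),
                 meta = list(seed = config$seed, photons = config$photons,
                             batches = config$batches,
                             config_hash = config_hash(config),
                             grid = config$grid, keep = keep)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("<mc_result> launched %s | absorbed %s | escaped %s | cap %s | kept %s\n",
              format(ct[["launched"]], big.mark = ","), ct[["absorbed"]],
              ct[["escaped"]], ct[["iteration_cap"]], ct[["kept"]]))
  invisible(x)
}

# Stable hash of the scientific content of a config (not the precomputed
# table): serialize to JSON and md5 the bytes.
config_hash <- function(config) {
  key <- config[c("photons", "batches", "seed", "max_iterations")]
  key$grid <- config$grid$wavelength_nm
  key$source <- unclass(config$source)
  key$detector <- if (!is.null(config$detector)) unclass(config$detector)
  key$geometry <- engine_geom(config$geometry)
  key$materials <- lapply(config$materials, function(m)
    lapply(unclass(m), function(f) if (inherits(f, "mc_spectrum") ||
                                       inherits(f, "mc_dispersion"))
      unclass(f) else f))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(key, digits = NA, auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}

#' Launch a photon (reference implementation)
#'
#' Draws a photon's initial position and direction from a source
#' specification using an explicit uniform-variate supply; used by the
#' scalar reference engine and for testing the launch distribution.
#'
#' @param source an [source_spec()].
#' @param next_u function() returning the next uniform(0,1) variate.
#' @return list with `position` (mm) and `direction` (unit vector).
#' @export
launch_photon <- function(source, next_u) {
  pos <- c(source$cx_mm, source$cy_mm, -source$z0_mm)
  if (source$std_mm > 0) {
    repeat {
      u1 <- next_u(); u2 <- next_u()
      r <- source$std_mm * sqrt(-2 * log(1 - u1))
      x <- r * cos(2 * pi * u2); y <- r * sin(2 * pi * u2)
      if (source$radius_mm <= 0 || x^2 + y^2 <= source$radius_mm^2) break
    }
    pos[1] <- pos[1] + x; pos[2] <- pos[2] + y
  }
  dir <- c(0, 0, 1)
  if (source$cone_deg > 0) {
    u3 <- next_u(); u4 <- next_u()
    ct <- 1 - u3 * (1 - cos(source$cone_deg * pi / 180))
    st <- sqrt(1 - ct^2); ph <- 2 * pi * u4
    dir <- c(st * cos(ph), st * sin(ph), ct)
  }
  list(position = pos, direction = dir)
}

# internal mirrors of the engine's cosine-parameterized helpers -----------

fresnel_cos_ref <- function(n1, n2, c1) {
  s1 <- sqrt(1 - c1 * c1)
  s2 <- n1 * s1 / n2
  if (s2 >= 1) return(1)
  c2 <- sqrt(1 - s2 * s2)
  rs <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
  rp <- (n1 * c2 - n2 * c1) / (n1 * c2 + n2 * c1)
  0.5 * (rs * rs + rp * rp)
}

deflect_ref <- function(u, ct, st, cp, sp) {
  if (abs(u[3]) > 1 - 1e-12) {
    v <- c(st * cp, st * sp, ct * if (u[3] >= 0) 1 else -1)
  } else {
    den <- sqrt(1 - u[3] * u[3])
    v <- c(st * (u[1] * u[3] * cp - u[2] * sp) / den + u[1] * ct,
           st * (u[2] * u[3] * cp + u[1] * sp) / den + u[2] * ct,
           -st * cp * den + u[3] * ct)
  }
  v / sqrt(v[1] * v[1] + v[2] * v[2] + v[3] * v[3])
}

#' Propagate one photon with the scalar reference engine
#'
#' A plain-R transcription of the per-photon event loop, driven by an
#' explicit variate supply.  It exists to validate the compiled engine:
#' replaying the variate stream recorded by the compiled engine through this
#' function must reproduce the photon record exactly.
#'
#' @param config an [run_config()].
#' @param next_u function() returning the next uniform(0,1) variate.
#' @return One-row data.frame with the same columns as
#'   [run_simulation()] records (minus `batch`).
#' @export
propagate_photon <- function(config, next_u) {
  stopifnot(inherits(config, "mc_config"))
  tab <- config$table
  geom <- config$geometry
  K <- length(config$grid$wavelength_nm)
  eps_push <- 1e-7
  lp <- launch_photon(config$source, next_u)
  pos <- lp$position; u <- lp$direction
  wl <- 1L  # 1-based; 1 = source wavelength
  n_raman <- 0L; n_fluor <- 0L; raman_z <- NA_real_
  iters <- 0L; status <- NA_integer_
  # Raman conversion opportunities exist at collision sites only (not at
  # entry or boundary touch points); mirrors the compiled engine
  at_collision <- FALSE
  reach <- geometry_reach(geom)
  repeat {
    iters <- iters + 1L
    if (iters > config$max_iterations) { status <- 3L; break }
    m <- material_at(geom, pos)
    if (m == 0L) {
      h <- first_interface(geom, pos, u, reach)
      if (is.null(h)) { status <- 2L; break }
      pos <- pos + h$distance * u
      c1 <- min(1, max(-1, -sum(u * h$normal)))
      n2 <- if (h$material_after == 0L) 1 else tab$n[wl, h$material_after]
      R <- fresnel_cos_ref(1, n2, c1)
      xi7 <- next_u()
      if (xi7 < R) {
        u <- u + 2 * c1 * h$normal
      } else {
        eta <- 1 / n2
        c2 <- sqrt(1 - eta * eta * (1 - c1 * c1))
        u <- eta * u + (eta * c1 - c2) * h$normal
      }
      u <- u / sqrt(u[1]^2 + u[2]^2 + u[3]^2)
      pos <- pos + eps_push * u
      at_collision <- FALSE
      next
    }
    if (at_collision) {
      xi6 <- next_u()
      kR <- sample_shift_wavelength(xi6, tab$cdf_R[, m])
      if (!is.na(kR)) {
        wl <- kR
        if (n_raman == 0L) raman_z <- pos[3]
        n_raman <- n_raman + 1L
      }
    }
    mu_s <- tab$mu_s[wl, m]; mu_a <- tab$mu_a[wl, m]
    g <- tab$g[wl, m]; n1 <- tab$n[wl, m]
    xi1 <- next_u(); l <- -log(1 - xi1) / mu_s
    h <- first_interface(geom, pos, u, l)
    ltrav <- if (is.null(h)) l else h$distance
    pos <- pos + ltrav * u
    xi4 <- next_u()
    if (xi4 < 1 - exp(-mu_a * ltrav)) {
      xi5 <- next_u()
      kF <- sample_shift_wavelength(xi5, tab$cdf_F[, m])
      if (is.na(kF)) { status <- 1L; break }
      wl <- kF
      n_fluor <- n_fluor + 1L
      xa <- next_u(); xb <- next_u()
      ctf <- 2 * xa - 1; stf <- sqrt(1 - ctf * ctf); phf <- 2 * pi * xb
      u <- c(stf * cos(phf), stf * sin(phf), ctf)
      pos <- pos + eps_push * u
      at_collision <- TRUE
      next
    }
    if (is.null(h)) {  # completed step: scatter at the new collision site
      xi2 <- next_u(); phi <- 2 * pi * xi2
      xi3 <- next_u()
      if (abs(g) < 1e-6) {
        ct <- 2 * xi3 - 1
      } else {
        f <- (1 - g * g) / (1 - g + 2 * g * xi3)
        ct <- min(1, max(-1, (1 + g * g - f * f) / (2 * g)))
      }
      u <- deflect_ref(u, ct, sqrt(1 - ct * ct), cos(phi), sin(phi))
      at_collision <- TRUE
    }
    if (!is.null(h)) {
      c1 <- min(1, max(-1, -sum(u * h$normal)))
      n2 <- if (h$material_after == 0L) 1 else tab$n[wl, h$material_after]
      R <- fresnel_cos_ref(n1, n2, c1)
      xi7 <- next_u()
      if (xi7 < R) {
        u <- u + 2 * c1 * h$normal
      } else {
        eta <- n1 / n2
        c2 <- sqrt(1 - eta * eta * (1 - c1 * c1))
        u <- eta * u + (eta * c1 - c2) * h$normal
      }
      u <- u / sqrt(u[1]^2 + u[2]^2 + u[3]^2)
      pos <- pos + eps_push * u
      at_collision <- FALSE
    }
  }
  data.frame(status = as.numeric(status), x = pos[1], y = pos[2], z = pos[3],
             ux = u[1], uy = u[2], uz = u[3], wl_index = as.numeric(wl),
             n_raman = as.numeric(n_raman), n_fluor = as.numeric(n_fluor),
             raman_z = raman_z, iterations = as.numeric(iters))
}

#' Run the compiled engine with variate recording or replay (testing aid)
#'
#' @param config an [run_config()]; one batch of `config$photons` photons.
#' @param batch batch index (seeds the substream).
#' @param record if `TRUE`, return the consumed uniform variates per photon.
#' @param replay optional list of per-photon variate vectors to consume
#'   instead of the RNG.
#' @return list with `records`, `counts` and (if recording) `variates`.
#' @export
run_batch_traced <- function(config, batch = 1L, record = FALSE,
                             replay = NULL) {
  stopifnot(inherits(config, "mc_config"))
  tab <- config$table
  mats <- list(mu_s = tab$mu_s, mu_a = tab$mu_a, g = tab$g, n = tab$n,
               cdf_R = tab$cdf_R, cdf_F = tab$cdf_F)
  out <- mc_batch_cpp(engine_geom(config$geometry), mats,
                      config$source[c("radius_mm", "std_mm", "cone_deg",
                                      "z0_mm", "cx_mm", "cy_mm")],
                      list(), config$photons, as.double(config$seed),
                      as.integer(batch), config$max_iterations, 0L, replay,
                      record, FALSE)
  out$records <- as.data.frame(out$records)
  out
}
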