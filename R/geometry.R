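#' Medium geometries: layered slabs and voxel label volumes
#'
#' A geometry maps a position (mm) to a material id, with 0 meaning the
#' surrounding void (vacuum).  Coordinates are right-handed with the z axis
#' pointing *into* the medium and the top surface at z = 0; depth is z >= 0.
#'
#' `layered_geometry` describes a stack of layers between plane boundaries
#' `boundaries_mm[1] < ... < boundaries_mm[L+1]`, laterally bounded by
#' `|x| <= half_x_mm`, `|y| <= half_y_mm`.
#'
#' `voxel_geometry` describes a label volume: integer array `labels`
#' (dimensions nx, ny, nz) with voxel pitch `pitch_mm`; voxel (i, j, k)
#' (0-based) owns the half-open cube `[origin + i*pitch, origin + (i+1)*pitch)`.
#' Label 0 is void.
#'
#' @param boundaries_mm strictly increasing z positions of layer boundaries.
#' @param material_ids integer id per layer (length `length(boundaries_mm)-1`).
#' @param half_x_mm,half_y_mm lateral half extents (mm).
#' @return An object of class `mc_geometry`.
#' @export
layered_geometry <- function(boundaries_mm, material_ids,
                             half_x_mm = 10, half_y_mm = half_x_mm) {
  boundaries_mm <- as.numeric(boundaries_mm)
  material_ids <- as.integer(material_ids)
  if (length(boundaries_mm) != length(material_ids) + 1L)
    stop("need one more boundary than layers")
  if (any(diff(boundaries_mm) <= 0))
    stop("layer boundaries must be strictly increasing")
  if (any(material_ids < 1L)) stop("layer material ids must be >= 1")
  stopifnot(half_x_mm > 0, half_y_mm > 0)
  structure(list(kind = "LAYERED", boundaries = boundaries_mm,
                 ids = material_ids, half_x = half_x_mm, half_y = half_y_mm),
            class = "mc_geometry")
}

#' @param labels integer 3-d array (nx x ny x nz) of material labels, 0 = void.
#' @param pitch_mm voxel edge length (mm), > 0.
#' @param origin_mm length-3 position of the voxel (0,0,0) corner; the default
#'   centers the volume laterally and puts its top face at z = 0.
#' @rdname layered_geometry
#' @export
voxel_geometry <- function(labels, pitch_mm, origin_mm = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-d array")
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be nonnegative integers")
  stopifnot(pitch_mm > 0)
  d <- dim(labels)
  if (is.null(origin_mm))
    origin_mm <- c(-d[1] * pitch_mm / 2, -d[2] * pitch_mm / 2, 0)
  structure(list(kind = "VOXEL", labels = array(as.integer(labels), d),
                 dims = d, pitch = pitch_mm, origin = as.numeric(origin_mm)),
            class = "mc_geometry")
}

#' @export
print.mc_geometry <- function(x, ...) {
  if (x$kind == "LAYERED") {
    cat(sprintf("<mc_geometry LAYERED> %d layer(s), z %.4g-%.4g mm, lateral %.4g x %.4g mm\n",
                length(x$ids), x$boundaries[1], max(x$boundaries),
                2 * x$half_x, 2 * x$half_y))
  } else {
    cat(sprintf("<mc_geometry VOXEL> %d x %d x %d voxels @ %.4g um pitch\n",
                x$dims[1], x$dims[2], x$dims[3], 1000 * x$pitch))
  }
  invisible(x)
}

#' Look up the material at a position
#'
#' @param geom an [layered_geometry()] or [voxel_geometry()].
#' @param p numeric length-3 position (mm).
#' @return integer material id; 0 for void (outside all structures).
#' @export
material_at <- function(geom, p) {
  stopifnot(inherits(geom, "mc_geometry"))
  if (geom$kind == "LAYERED") {
    if (abs(p[1]) > geom$half_x || abs(p[2]) > geom$half_y) return(0L)
    b <- geom$boundaries
    if (p[3] < b[1] || p[3] >= b[length(b)]) return(0L)
    i <- findInterval(p[3], b)  # b[i] <= z < b[i+1]
    geom$ids[i]
  } else {
    i <- floor((p - geom$origin) / geom$pitch)
    if (any(i < 0) || any(i >= geom$dims)) return(0L)
    geom$labels[i[1] + 1L, i[2] + 1L, i[3] + 1L]
  }
}

# Reach beyond which a photon in void cannot re-enter the geometry.
geometry_reach <- function(geom) {
  if (geom$kind == "LAYERED") {
    ext <- c(2 * geom$half_x, 2 * geom$half_y,
             geom$boundaries[length(geom$boundaries)] - geom$boundaries[1])
  } else {
    ext <- geom$dims * geom$pitch
  }
  2 * sqrt(sum(ext^2)) + 1
}

# Axis-aligned bounding box of the occupied region, list(lo, hi).
geometry_bbox <- function(geom) {
  if (geom$kind == "LAYERED") {
    list(lo = c(-geom$half_x, -geom$half_y, geom$boundaries[1]),
         hi = c(geom$half_x, geom$half_y, geom$boundaries[length(geom$boundaries)]))
  } else {
    list(lo = geom$origin, hi = geom$origin + geom$dims * geom$pitch)
  }
}

#' Find the first material interface along a segment
#'
#' Walks the segment from `origin` along unit vector `direction` for at most
#' `step` mm and returns the nearest point where the material id changes,
#' or `NULL` if the whole segment stays in one material.  Layered geometries
#' use closed-form plane intersections; voxel geometries use exact 3-D DDA
#' traversal.  The returned `normal` is the unit normal of the crossed
#' surface oriented against the direction of travel (so that
#' `-sum(direction * normal)` is the cosine of the incidence angle).
#'
#' @param geom an `mc_geometry`.
#' @param origin length-3 position (mm).
#' @param direction unit length-3 vector.
#' @param step maximum distance to search (mm, >= 0).
#' @return `NULL`, or a list with `distance` (mm), `normal` (length-3),
#'   `material_before`, `material_after` (integer ids).
#' @export
first_interface <- function(geom, origin, direction, step) {
  stopifnot(inherits(geom, "mc_geometry"), step >= 0)
  if (abs(sum(direction^2) - 1) > 1e-9) stop("direction must be a unit vector")
  m0 <- material_at(geom, origin)
  eps <- 1e-9
  if (geom$kind == "LAYERED") {
    ts <- numeric(0)
    planes <- list()
    add <- function(t, nrm) {
      if (t > eps && t <= step) {
        ts[[length(ts) + 1L]] <<- t
        planes[[length(planes) + 1L]] <<- nrm
      }
    }
    for (zb in geom$boundaries)
      if (direction[3] != 0)
        add((zb - origin[3]) / direction[3], c(0, 0, -sign(direction[3])))
    for (xb in c(-geom$half_x, geom$half_x))
      if (direction[1] != 0)
        add((xb - origin[1]) / direction[1], c(-sign(direction[1]), 0, 0))
    for (yb in c(-geom$half_y, geom$half_y))
      if (direction[2] != 0)
        add((yb - origin[2]) / direction[2], c(0, -sign(direction[2]), 0))
    if (!length(ts)) return(NULL)
    ord <- order(unlist(ts))
    for (k in ord) {
      t <- ts[[k]]
      m1 <- material_at(geom, origin + (t + eps) * direction)
      if (m1 != m0)
        return(list(distance = t, normal = planes[[k]],
                    material_before = m0, material_after = m1))
    }
    return(NULL)
  }
  # VOXEL: clip to the volume AABB, then DDA
  bb <- geometry_bbox(geom)
  ten <- -Inf; tex <- Inf; enter_axis <- 0L
  for (a in 1:3) {
    if (direction[a] == 0) {
      if (origin[a] < bb$lo[a] || origin[a] >= bb$hi[a]) { ten <- Inf; break }
    } else {
      t1 <- (bb$lo[a] - origin[a]) / direction[a]
      t2 <- (bb$hi[a] - origin[a]) / direction[a]
      tlo <- min(t1, t2); thi <- max(t1, t2)
      if (tlo > ten) { ten <- tlo; enter_axis <- a }
      tex <- min(tex, thi)
    }
  }
  if (ten > tex || ten > step) {
    return(NULL)  # segment never inside the volume: all void, m0 must be 0
  }
  p <- geom$pitch; o <- geom$origin; d <- geom$dims
  if (ten > eps && m0 == 0L) {
    # entering the volume from outside: first crossing is the AABB face
    m1 <- material_at(geom, origin + (ten + eps) * direction)
    if (m1 != 0L) {
      nrm <- c(0, 0, 0); nrm[enter_axis] <- -sign(direction[enter_axis])
      return(list(distance = ten, normal = nrm,
                  material_before = 0L, material_after = m1))
    }
  }
  t0 <- max(ten, 0)
  start <- origin + (t0 + eps) * direction
  iv <- floor((start - o) / p)
  if (any(iv < 0) || any(iv >= d)) iv <- pmin(pmax(iv, 0), d - 1)
  stepv <- sign(direction); stepv[stepv == 0] <- 1L
  tmax <- numeric(3); tdelta <- numeric(3)
  for (a in 1:3) {
    if (direction[a] == 0) { tmax[a] <- Inf; tdelta[a] <- Inf }
    else {
      nextb <- o[a] + (iv[a] + (direction[a] > 0)) * p
      tmax[a] <- (nextb - origin[a]) / direction[a]
      tdelta[a] <- p / abs(direction[a])
    }
  }
  tend <- min(step, tex)
  repeat {
    a <- which.min(tmax)
    t <- tmax[a]
    if (t > tend) break
    iv[a] <- iv[a] + stepv[a]
    if (any(iv < 0) || any(iv >= d)) {
      # leaving the volume into void
      if (m0 != 0L && t <= step) {
        nrm <- c(0, 0, 0); nrm[a] <- -sign(direction[a])
        return(list(distance = t, normal = nrm,
                    material_before = m0, material_after = 0L))
      }
      return(NULL)
    }
    m1 <- geom$labels[iv[1] + 1L, iv[2] + 1L, iv[3] + 1L]
    if (m1 != m0) {
      nrm <- c(0, 0, 0); nrm[a] <- -sign(direction[a])
      return(list(distance = t, normal = nrm,
                  material_before = m0, material_after = m1))
    }
    tmax[a] <- tmax[a] + tdelta[a]
  }
  NULL
}

#' Load a voxel label volume from a stack of grayscale images
#'
#' Slices are 8/16-bit grayscale PNG or TIFF files, one per z level, in
#' alphabetical filename order; pixel values are material labels (0 = void).
#' All slices must share one shape and contain integer values.
#'
#' @param paths character vector of image files, or a directory containing
#'   them.
#' @param pitch_mm voxel pitch (mm).
#' @param origin_mm optional origin (see [voxel_geometry()]).
#' @return An `mc_geometry` of kind VOXEL.
#' @export
load_label_volume <- function(paths, pitch_mm, origin_mm = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE)
  paths <- sort(paths)
  if (!length(paths)) stop("no image slices found")
  read_slice <- function(f) {
    ext <- tolower(tools::file_ext(f))
    img <- switch(ext,
      png = { requireNamespace("png", quietly = TRUE) || stop("png package required")
              png::readPNG(f) },
      tif = , tiff = { requireNamespace("tiff", quietly = TRUE) || stop("tiff package required")
              tiff::readTIFF(f) },
      stop("unsupported slice format: ", ext))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    # readers scale to [0,1]; recover integer labels (8- or 16-bit)
    lab <- round(img * 255)
    if (max(abs(img * 255 - lab)) > 1e-6) {
      lab <- round(img * 65535)
      if (max(abs(img * 65535 - lab)) > 1e-3)
        stop("non-integer pixel values in ", f)
    }
    lab
  }
  slices <- lapply(paths, read_slice)
  shp <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
    stop("ragged image stack: slices differ in shape")
  labels <- array(0L, c(shp[2], shp[1], length(slices)))  # x, y, z
  for (k in seq_along(slices)) labels[, , k] <- as.integer(t(slices[[k]]))
  voxel_geometry(labels, pitch_mm, origin_mm)
}

#' Rasterize a layered geometry onto a voxel grid
#'
#' Utility for consistency testing and for building the voxel replicas of
#' layered phantoms: samples [material_at()] at voxel centers.
#'
#' @param geom a LAYERED `mc_geometry`.
#' @param dims integer length-3 voxel counts.
#' @return A VOXEL `mc_geometry` covering the same bounding box.
#' @export
rasterize_layered <- function(geom, dims = c(64, 64, 64)) {
  stopifnot(geom$kind == "LAYERED")
  bb <- geometry_bbox(geom)
  ext <- bb$hi - bb$lo
  pitch <- max(ext / dims)
  labels <- array(0L, dims)
  xc <- bb$lo[1] + (seq_len(dims[1]) - 0.5) * pitch
  yc <- bb$lo[2] + (seq_len(dims[2]) - 0.5) * pitch
  zc <- bb$lo[3] + (seq_len(dims[3]) - 0.5) * pitch
  inside <- outer(abs(xc) <= geom$half_x, abs(yc) <= geom$half_y)
  b <- geom$boundaries
  for (k in seq_len(dims[3])) {
    if (zc[k] < b[1] || zc[k] >= b[length(b)]) next
    labels[, , k] <- geom$ids[findInterval(zc[k], b)] * inside
  }
  voxel_geometry(labels, pitch, c(bb$lo[1], bb$lo[2], bb$lo[3]))
}
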