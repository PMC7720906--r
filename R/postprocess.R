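#' Raman sensing depth: the (1 - X) quantile of conversion depth
#'
#' The sensing depth d_X is the depth *beyond which* a fraction X of all
#' detected Raman photons were generated, i.e. the (1 - X) empirical
#' quantile of the conversion-depth sample (nearest-rank rule: sort
#' ascending, take the element at rank `ceiling((1 - X) * N)`).  Under this
#' convention d_90 <= d_75: requiring more of the signal to originate below
#' the quoted depth pushes the quoted depth up toward the surface.
#'
#' @param depths_mm numeric vector of conversion depths (mm), nonempty.
#' @param X fraction in (0, 1); e.g. 0.75 for the 75 percent sensing depth.
#' @param weights optional nonnegative weights (e.g. conversion
#'   probabilities from the conditional-expectation estimator, see
#'   [raman_depth_sample()]); the quantile then uses the smallest depth
#'   whose cumulative weight fraction reaches `1 - X`, which reduces to the
#'   nearest-rank rule for equal weights.
#' @return depth in mm.
#' @export
sensing_depth <- function(depths_mm, X = 0.75, weights = NULL) {
  if (!length(depths_mm)) stop("empty depth sample; check n_detected first")
  stopifnot(X > 0, X < 1, all(depths_mm >= 0))
  if (is.null(weights)) {
    s <- sort(depths_mm)
    return(s[max(1L, ceiling((1 - X) * length(s)))])
  }
  stopifnot(length(weights) == length(depths_mm), all(weights >= 0),
            sum(weights) > 0)
  o <- order(depths_mm)
  cw <- cumsum(weights[o]) / sum(weights)
  depths_mm[o][which(cw >= (1 - X))[1]]
}

#' Depth metrics with bootstrap confidence intervals
#'
#' For the direct (unweighted) estimator, depths are resampled i.i.d.  For
#' the weighted conditional-expectation estimator, whole trajectories are
#' resampled (cluster bootstrap over `groups`), since the weights of one
#' trajectory's conversion opportunities are dependent.
#'
#' @param depths_mm detected-Raman conversion depths (mm).
#' @param boot number of bootstrap resamples.
#' @param conf confidence level.
#' @param weights,groups optional weights and trajectory ids aligned with
#'   `depths_mm` (see [raman_depth_sample()]).
#' @return list with `d75`, `d90` (mm), their `conf` percentile bootstrap
#'   intervals (`d75_ci`, `d90_ci`), and `n_detected`.
#' @export
depth_metrics <- function(depths_mm, boot = 500, conf = 0.95, weights = NULL,
                          groups = NULL) {
  n <- length(depths_mm)
  if (!n) stop("empty depth sample")
  d75 <- sensing_depth(depths_mm, 0.75, weights)
  d90 <- sensing_depth(depths_mm, 0.90, weights)
  a <- (1 - conf) / 2
  if (is.null(weights)) {
    bs <- matrix(sample(depths_mm, n * boot, replace = TRUE), nrow = n)
    b75 <- apply(bs, 2, function(d) sensing_depth(d, 0.75))
    b90 <- apply(bs, 2, function(d) sensing_depth(d, 0.90))
    n_eff <- n
  } else {
    if (is.null(groups)) groups <- seq_len(n)
    idx_by_g <- split(seq_len(n), groups)
    ng <- length(idx_by_g)
    b75 <- b90 <- numeric(boot)
    for (b in seq_len(boot)) {
      pick <- unlist(idx_by_g[sample.int(ng, ng, replace = TRUE)],
                     use.names = FALSE)
      b75[b] <- sensing_depth(depths_mm[pick], 0.75, weights[pick])
      b90[b] <- sensing_depth(depths_mm[pick], 0.90, weights[pick])
    }
    n_eff <- ng
  }
  list(d75 = d75, d90 = d90,
       d75_ci = unname(stats::quantile(b75, c(a, 1 - a))),
       d90_ci = unname(stats::quantile(b90, c(a, 1 - a))),
       n_detected = n_eff)
}

#' Rolling-ball baseline estimate of a spectrum
#'
#' One-dimensional grayscale morphological opening with a flat structuring
#' window of `2 * half_width + 1` bins (moving minimum followed by moving
#' maximum).  The opening tracks broad backgrounds (e.g. residual
#' fluorescence) but cannot reach into peaks narrower than the window, so
#' `spectrum - baseline` isolates narrow Raman peaks.  The baseline never
#' exceeds the spectrum.
#'
#' @param values numeric spectrum values (or an [mc_spectrum()]).
#' @param half_width window half-width in bins (>= 1).  Choose roughly 10x
#'   the widest expected Raman peak FWHM.
#' @return numeric baseline (same length), or an `mc_spectrum` if the input
#'   was one.
#' @export
rolling_ball_baseline <- function(values, half_width) {
  s <- NULL
  if (inherits(values, "mc_spectrum")) { s <- values; values <- s$value }
  n <- length(values)
  stopifnot(half_width >= 1)
  w <- 2 * as.integer(half_width) + 1L
  if (w > n) stop("rolling-ball window larger than the spectrum")
  run <- function(x, f) {
    # windows clipped at the edges
    vapply(seq_len(n), function(i)
      f(x[max(1L, i - half_width):min(n, i + half_width)]), numeric(1))
  }
  base <- run(run(values, min), max)
  if (!is.null(s)) mc_spectrum(s$wavelength_nm, pmax(base, 0)) else base
}

#' Standard normal variate (SNV) normalization
#'
#' Centers a spectrum to zero mean and scales to unit sample (N - 1)
#' standard deviation.  Affine-invariant: `a * s + b` normalizes to the same
#' output as `s` for any a > 0.
#'
#' @param values numeric spectrum values (>= 2 bins, nonzero variance).
#' @return numeric normalized values.
#' @export
snv_normalize <- function(values) {
  if (inherits(values, "mc_spectrum")) values <- values$value
  if (length(values) < 2) stop("SNV needs at least 2 bins")
  sd <- stats::sd(values)
  if (!is.finite(sd) || sd == 0) stop("SNV undefined for zero-variance spectrum")
  (values - mean(values)) / sd
}

#' Raman sensing-depth study over an optical-property grid
#'
#' Runs one simulation per (mu_a, mu_s', rho_R) combination on the
#' semi-infinite-slab depth-study medium (see [make_depth_medium()]),
#' collects the conversion depths of detected Raman photons, and reports the
#' 75 / 90 percent sensing depths with bootstrap confidence intervals.
#'
#' @param mu_a_mm,mu_s_prime_mm,rho_R numeric vectors; the full grid
#'   (crossing) of values is simulated.  `rho_R` is the per-wavelength
#'   conversion rate (see [make_depth_medium()]).
#' @param photons,batches photons per batch and batch count per grid point.
#' @param seed base RNG seed; each grid point derives its own sub-seed.
#' @param g,n anisotropy and refractive index of the medium.
#' @param min_detected grid points with fewer detected Raman photons (for
#'   `"recorded"`) or accepted trajectories (for `"expected"`) are flagged
#'   unreliable (`reliable = FALSE`, metrics NA).
#' @param estimator depth estimator, see [raman_depth_sample()];
#'   `"expected"` (default) is exact for these wavelength-flat media and
#'   remains well-powered at realistic (tiny) Raman conversion rates.
#' @param boot bootstrap resamples for the confidence intervals.
#' @param progress print one line per grid point.
#' @param ... passed to [make_depth_medium()] (e.g. `representation`).
#' @return data.frame with columns mu_a_mm, mu_s_prime_mm, rho_R, d75_um,
#'   d90_um, d75_ci_lo, d75_ci_hi, d90_ci_lo, d90_ci_hi, n_detected,
#'   reliable.
#' @export
depth_study <- function(mu_a_mm, mu_s_prime_mm, rho_R, photons = 1e5,
                        batches = 1, seed = 1, g = 0.9, n = 1.4,
                        min_detected = 20,
                        estimator = c("expected", "recorded"), boot = 500,
                        progress = FALSE, ...) {
  estimator <- match.arg(estimator)
  grid_pts <- expand.grid(mu_a_mm = mu_a_mm, mu_s_prime_mm = mu_s_prime_mm,
                          rho_R = rho_R)
  out <- vector("list", nrow(grid_pts))
  for (i in seq_len(nrow(grid_pts))) {
    gp <- grid_pts[i, ]
    fx <- make_depth_medium(gp$mu_a_mm, gp$mu_s_prime_mm, gp$rho_R,
                            g = g, n = n, ...)
    cfg <- run_config(fx$geometry, fx$materials, grid = fx$grid,
                      source = fx$source, detector = fx$detector,
                      photons = photons, batches = batches,
                      seed = seed + 997L * (i - 1L))
    res <- run_simulation(cfg, keep = "accepted",
                          trace_depths = estimator == "expected")
    ds <- raman_depth_sample(res, fx$detector, rho_step = fx$rho_step_total,
                             estimator = estimator)
    nd <- length(unique(ds$traj))
    row <- data.frame(mu_a_mm = gp$mu_a_mm, mu_s_prime_mm = gp$mu_s_prime_mm,
                      rho_R = gp$rho_R, d75_um = NA_real_, d90_um = NA_real_,
                      d75_ci_lo = NA_real_, d75_ci_hi = NA_real_,
                      d90_ci_lo = NA_real_, d90_ci_hi = NA_real_,
                      n_detected = nd, reliable = nd >= min_detected)
    if (nd >= max(1, min_detected)) {
      wts <- if (estimator == "expected") ds$weight
      m <- with_seed(cfg$seed, depth_metrics(ds$depth_mm, boot = boot,
                                             weights = wts,
                                             groups = ds$traj))
      row$d75_um <- 1000 * m$d75; row$d90_um <- 1000 * m$d90
      row$d75_ci_lo <- 1000 * m$d75_ci[1]; row$d75_ci_hi <- 1000 * m$d75_ci[2]
      row$d90_ci_lo <- 1000 * m$d90_ci[1]; row$d90_ci_hi <- 1000 * m$d90_ci[2]
    }
    if (progress)
      message(sprintf(
        "depth_study %d/%d: mu_a=%g mu_s'=%g rho_R=%g -> n=%d d75=%.1f um",
        i, nrow(grid_pts), gp$mu_a_mm, gp$mu_s_prime_mm, gp$rho_R, nd,
        row$d75_um))
    out[[i]] <- row
  }
  do.call(rbind, out)
}

# evaluate expr under a temporary R RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Conversion depths of detected Raman photons
#'
#' @param result an `mc_result` from [run_simulation()].
#' @param det a [detector_spec()].
#' @return numeric vector of conversion depths (mm) for accepted records
#'   that Raman-shifted.
#' @export
detected_raman_depths <- function(result, det) {
  rec <- result$records
  ok <- accept(rec, det) & rec$n_raman > 0
  rec$raman_z[ok]
}

#' Detected-Raman conversion-depth sample (direct or conditional estimator)
#'
#' Two estimators of the conversion-depth distribution of detected Raman
#' photons:
#'
#' * `"recorded"` — the direct estimator: the recorded first-shift depth of
#'   every accepted record that actually Raman-shifted (weight 1 each).
#' * `"expected"` — the conditional-expectation estimator: in a medium whose
#'   optical properties are wavelength-flat (the depth-study media), a
#'   photon's trajectory is exactly independent of the Raman-shift lottery,
#'   so the expectation over the shift draws can be taken analytically: each
#'   conversion opportunity of an *accepted* trajectory (the z position of
#'   its k-th material step) contributes weight
#'   `rho * (1 - rho)^(k - 1)` — the probability that the first shift
#'   happens exactly there.  This computes the same distribution as
#'   `"recorded"` with every accepted trajectory contributing, which is
#'   decisive when `rho` is small (at rho = 1e-6 the direct estimator
#'   detects ~1 photon per 1e7 launched).  It requires
#'   `run_simulation(..., trace_depths = TRUE)`.
#'
#' @param result an `mc_result`.
#' @param det a [detector_spec()].
#' @param rho_step total per-step Raman conversion probability (needed for
#'   `"expected"`; e.g. the `rho_R_total` of [make_depth_medium()]).
#' @param estimator `"expected"` or `"recorded"`.
#' @return data.frame with columns `depth_mm`, `weight`, `traj` (trajectory
#'   id for cluster bootstrap); zero rows if nothing was detected.
#' @export
raman_depth_sample <- function(result, det, rho_step = NULL,
                               estimator = c("expected", "recorded")) {
  estimator <- match.arg(estimator)
  if (estimator == "recorded") {
    d <- detected_raman_depths(result, det)
    return(data.frame(depth_mm = d, weight = rep(1, length(d)),
                      traj = seq_along(d)))
  }
  if (is.null(result$depth_traces))
    stop("expected estimator needs run_simulation(trace_depths = TRUE)")
  if (is.null(rho_step) || rho_step < 0 || rho_step > 1)
    stop("expected estimator needs rho_step in [0, 1]")
  ok <- which(accept(result$records, det))
  if (!length(ok) || rho_step == 0)
    return(data.frame(depth_mm = numeric(0), weight = numeric(0),
                      traj = integer(0)))
  tr <- result$depth_traces[ok]
  lens <- lengths(tr)
  keep <- lens > 0
  tr <- tr[keep]; lens <- lens[keep]
  depth <- unlist(tr, use.names = FALSE)
  k <- sequence(lens)
  data.frame(depth_mm = depth,
             weight = rho_step * (1 - rho_step)^(k - 1),
             traj = rep(seq_along(tr), lens))
}
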