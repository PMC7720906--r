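test_that("sensing depth implements the (1 - X) nearest-rank quantile", {
  expect_equal(sensing_depth(seq(10, 100, by = 10) / 1000, 0.75), 0.03)
  set.seed(401)
  u <- stats::runif(2e5)
  expect_equal(sensing_depth(u, 0.75), 0.25, tolerance = 0.01)
  e <- stats::rexp(2e5)
  expect_equal(sensing_depth(e, 0.90), stats::qexp(0.10), tolerance = 0.02)
  expect_error(sensing_depth(numeric(0)), "empty")
  # quantile ordering under this convention
  for (i in 1:20) {
    s <- stats::rexp(50, 3)
    expect_gte(sensing_depth(s, 0.75), sensing_depth(s, 0.90))
  }
})

test_that("weighted sensing depth reduces to nearest rank for equal weights", {
  set.seed(402)
  for (i in 1:20) {
    s <- stats::runif(37)
    expect_equal(sensing_depth(s, 0.75, weights = rep(2, 37)),
                 sensing_depth(s, 0.75))
    expect_equal(sensing_depth(s, 0.9, weights = rep(0.1, 37)),
                 sensing_depth(s, 0.9))
  }
  # weights concentrate the distribution: all mass on one point
  expect_equal(sensing_depth(c(1, 2, 3), 0.75, weights = c(0, 1, 0)), 2)
})

test_that("rolling-ball baseline is a grayscale opening below the spectrum", {
  const <- rep(4, 50)
  expect_equal(rolling_ball_baseline(const, 5), const)
  spike <- const; spike[25] <- 9
  base <- rolling_ball_baseline(spike, 5)
  expect_equal(base, const)             # opening removes the narrow maximum
  resid <- spike - base
  expect_equal(which(resid > 0), 25L)
  expect_error(rolling_ball_baseline(rep(1, 5), 3), "window")

  # broad background + narrow peaks: residual keeps the peak positions
  x <- seq_len(120)
  bg <- 50 * exp(-0.5 * ((x - 60) / 45)^2)
  pk <- c(20, 57, 95)
  spec <- bg
  for (p in pk) spec <- spec + 8 / (1 + ((x - p) / 1.5)^2)
  hw <- 8L
  base2 <- rolling_ball_baseline(spec, hw)
  # independent direct computation of erosion-then-dilation
  ero <- vapply(x, function(i)
    min(spec[max(1, i - hw):min(120, i + hw)]), numeric(1))
  dil <- vapply(x, function(i)
    max(ero[max(1, i - hw):min(120, i + hw)]), numeric(1))
  expect_equal(base2, dil)
  expect_true(all(base2 <= spec + 1e-12))
  resid2 <- spec - base2
  # local maxima of the residual above half the peak height recover the
  # input peak positions
  locmax <- which(resid2 > c(-Inf, resid2[-120]) &
                  resid2 >= c(resid2[-1], -Inf) & resid2 > 4)
  expect_equal(locmax, pk)
})

test_that("SNV normalization is exact and affine invariant", {
  expect_equal(snv_normalize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(403)
  s <- stats::runif(80)
  out <- snv_normalize(s)
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(stats::sd(out) - 1), 1e-12)
  expect_equal(snv_normalize(3.7 * s + 11), out)
  expect_error(snv_normalize(rep(2, 10)), "zero-variance")
  expect_error(snv_normalize(1), "2 bins")
})

test_that("recorded and expected depth estimators agree at a workable rate", {
  # at rho large enough for the direct estimator to be well powered, the two
  # estimators target the same distribution (the trajectory is independent
  # of the shift lottery in this wavelength-flat medium)
  fx <- make_depth_medium(0.1, 1, 1e-3)  # per-step total 0.1
  cfg <- run_config(fx$geometry, fx$materials, grid = fx$grid,
                    source = fx$source, detector = fx$detector,
                    photons = 4e4, seed = 47)
  res <- run_simulation(cfg, keep = "accepted", trace_depths = TRUE)
  rec <- raman_depth_sample(res, fx$detector, estimator = "recorded")
  exp_ <- raman_depth_sample(res, fx$detector, rho_step = fx$rho_step_total,
                             estimator = "expected")
  expect_gt(nrow(rec), 50)
  d75_rec <- sensing_depth(rec$depth_mm, 0.75)
  d75_exp <- sensing_depth(exp_$depth_mm, 0.75, exp_$weight)
  set.seed(48)
  m <- depth_metrics(rec$depth_mm, boot = 300)
  # recorded estimate's bootstrap CI must cover the expected-estimator value
  expect_gt(d75_exp, m$d75_ci[1] * 0.8)
  expect_lt(d75_exp, m$d75_ci[2] * 1.2)
  expect_equal(d75_rec, d75_exp, tolerance = 0.35)
})

test_that("depth_study flags unreliable grid points and handles rho = 0", {
  d0 <- depth_study(0.5, 2, 0, photons = 2000, seed = 51)
  expect_equal(d0$n_detected, 0)
  expect_false(d0$reliable)
  expect_true(is.na(d0$d75_um))
  d1 <- depth_study(0.5, 2, 1e-3, photons = 5000, seed = 53,
                    min_detected = 10)
  expect_true(d1$reliable)
  expect_true(d1$d75_ci_lo <= d1$d75_um && d1$d75_um <= d1$d75_ci_hi)
  expect_gte(d1$d75_um, d1$d90_um)
})

test_that("doubling a small Raman rate doubles conversions per launched photon", {
  n_conv <- vapply(c(5e-4, 1e-3), function(rho) {
    cfg <- thin_slab_config(photons = 3e4, seed = 57, rho_R_total = rho)
    sum(run_simulation(cfg, keep = "all")$records$n_raman)
  }, numeric(1))
  ratio <- n_conv[2] / n_conv[1]
  se <- ratio * sqrt(1 / n_conv[1] + 1 / n_conv[2])
  expect_lt(abs(ratio - 2), 3 * se)
})
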