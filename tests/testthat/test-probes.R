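mk_rec <- function(x = 0.25, y = 0, z = -1e-7, ux = 0, uy = 0, uz = -1,
                   status = 2, wl = 5) {
  data.frame(status = status, x = x, y = y, z = z, ux = ux, uy = uy,
             uz = uz, wl_index = wl, n_raman = 1, n_fluor = 0,
             raman_z = 0.1, iterations = 10)
}

test_that("acceptance applies the annulus and the angular cut", {
  det <- detector_spec(0.2, 0.3, 30)
  expect_true(accept(mk_rec(x = 0.25), det))
  expect_false(accept(mk_rec(x = 0), det))            # inside the bore
  expect_false(accept(mk_rec(x = 0.35), det))         # outside the annulus
  th <- 45 * pi / 180                                  # 45 deg off normal
  expect_false(accept(mk_rec(x = 0.25, ux = sin(th), uz = -cos(th)), det))
  th2 <- 20 * pi / 180
  expect_true(accept(mk_rec(x = 0.25, ux = sin(th2), uz = -cos(th2)), det))
  expect_false(accept(mk_rec(status = 1), det))        # absorbed
  expect_false(accept(mk_rec(z = 2, uz = 1), det))     # bottom exit
})

test_that("acceptance is invariant under rotation about the probe axis", {
  det <- detector_spec(0.2, 0.3, 30)
  set.seed(301)
  for (i in 1:100) {
    r <- stats::runif(1, 0, 0.5)
    phi <- stats::runif(1, 0, 2 * pi)
    th <- stats::runif(1, 0, pi / 2)
    psi <- stats::runif(1, 0, 2 * pi)
    base <- accept(mk_rec(x = r, y = 0, ux = sin(th) * cos(psi),
                          uy = sin(th) * sin(psi), uz = -cos(th)), det)
    rot <- accept(mk_rec(x = r * cos(phi), y = r * sin(phi),
                         ux = sin(th) * cos(psi + phi),
                         uy = sin(th) * sin(psi + phi), uz = -cos(th)), det)
    expect_identical(base, rot)
  }
})

test_that("nested apertures collect monotonically", {
  cfg <- thin_slab_config(photons = 4000, seed = 31, rho_R_total = 0.05)
  rec <- run_simulation(cfg, keep = "all")$records
  narrow <- sum(accept(rec, detector_spec(0.2, 0.3, 30)))
  wider_r <- sum(accept(rec, detector_spec(0.2, 0.5, 30)))
  wider_a <- sum(accept(rec, detector_spec(0.2, 0.3, 60)))
  expect_gte(wider_r, narrow)
  expect_gte(wider_a, narrow)
})

test_that("detected spectra bin accepted photons by final wavelength", {
  grid <- emission_grid()
  det <- detector_spec(0.2, 0.3, 30)
  empty <- bin_spectrum(mk_rec(status = 1), det, grid)
  expect_true(all(empty$counts == 0))
  one <- bin_spectrum(do.call(rbind, replicate(7, mk_rec(wl = 42),
                                               simplify = FALSE)),
                      det, grid, launched = 100)
  expect_equal(sum(one$counts), 7)
  expect_equal(one$counts[41], 7)  # emission bin 41 = grid index 42
  expect_equal(one$elastic_counts, 0)
  el <- bin_spectrum(mk_rec(wl = 1), det, grid)
  expect_equal(el$elastic_counts, 1)
  expect_equal(sum(el$counts), 0)
  bad <- mk_rec(wl = 500)
  expect_error(bin_spectrum(bad, det, grid), "off the emission grid")
})

test_that("per-bin counts show Poisson dispersion across independent seeds", {
  det <- detector_spec(0, 3, 90)  # wide aperture for workable bin counts
  grid <- emission_grid()
  counts <- sapply(1:20, function(s) {
    cfg <- thin_slab_config(photons = 6000, seed = 1000 + s,
                            rho_R_total = 0.5)
    cfg$detector <- det
    res <- run_simulation(cfg, keep = "accepted")
    bin_spectrum(res$records, det, grid, 6000)$counts
  })
  m <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  keep <- m >= 1
  expect_gt(sum(keep), 10)
  # index of dispersion ~ chi-square: pooled ratio near 1
  ratio <- sum(v[keep]) / sum(m[keep])
  nb <- sum(keep)
  expect_lt(abs(ratio - 1), 4 / sqrt(nb * 19 / 2))
})
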