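test_that("free-path sampling inverts the exponential CDF", {
  expect_equal(sample_step_length(0, 10), 0)
  expect_equal(sample_step_length(1 - exp(-1), 10), 0.1)
  expect_error(sample_step_length(0.5, 0), "mu_s")
  expect_error(sample_step_length(0.5, -2), "mu_s")

  set.seed(101)
  xi <- stats::runif(1e6)
  l <- sample_step_length(xi, 5)
  # exponential mean 1/mu_s, sd 1/mu_s: 3-sigma band on the sample mean
  expect_lt(abs(mean(l) - 0.2), 3 * 0.2 / sqrt(1e6))

  ks <- suppressWarnings(
    stats::ks.test(sample_step_length(stats::runif(1e5), 5),
                   stats::pexp, rate = 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("azimuth sampling is uniform on [0, 2*pi)", {
  expect_equal(sample_azimuth(0), 0)
  expect_equal(sample_azimuth(0.5), pi)
  set.seed(102)
  phi <- sample_azimuth(stats::runif(1e6))
  expect_lt(abs(mean(cos(phi))), 3 / sqrt(2 * 1e6))  # var(cos) = 1/2
})

test_that("Henyey-Greenstein polar sampling matches the inverse CDF", {
  expect_equal(sample_polar_hg(0, 0.9), pi)
  expect_equal(sample_polar_hg(1, 0.9), 0)
  expect_equal(sample_polar_hg(0.5, 0), pi / 2)
  # median deflection at g = 0.9, evaluated independently from the closed
  # form: cos(theta) = (1 + g^2 - ((1-g^2)/(1-g+2g*xi))^2) / (2g) = 0.98550
  expect_equal(cos(sample_polar_hg(0.5, 0.9)), 0.9855, tolerance = 1e-4)
  expect_error(sample_polar_hg(0.5, 1), "g")
})

test_that("HG mean cosine equals g for forward, backward and isotropic cases", {
  set.seed(103)
  for (g in c(-0.5, 0, 0.5, 0.9, 0.99)) {
    xi <- stats::runif(1e6)
    ct <- cos(sample_polar_hg(xi, g))
    se <- stats::sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se + 1e-9)
  }
})

test_that("Russian-roulette absorption follows the Beer-Lambert probability", {
  expect_false(any(absorption_occurs(stats::runif(100), 0, 5)))
  # mu_a * l tiny: threshold ~1e-4, xi = 0.5 survives
  expect_false(absorption_occurs(0.5, 0.001, 0.1))
  expect_true(absorption_occurs(5e-5, 0.001, 0.1))
  set.seed(104)
  l <- log(2)  # mu_a * l = ln 2 -> absorption probability 1/2
  frac <- mean(absorption_occurs(stats::runif(1e6), 1, l))
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(1e6))
})

test_that("wavelength-shift selection picks the shortest qualifying wavelength", {
  expect_true(is.na(sample_shift_wavelength(0.3, rep(0, 5))))
  cdf <- c(0.2e-6, 0.6e-6, 1.0e-6)
  expect_identical(sample_shift_wavelength(0.5e-6, cdf), 2L)
  expect_identical(sample_shift_wavelength(0.1e-6, cdf), 1L)
  expect_true(is.na(sample_shift_wavelength(0.5, cdf)))
})

test_that("Fresnel reflectance covers matched, normal and total-internal cases", {
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.3), 0)
  expect_equal(fresnel_reflectance(1, 1.4, 0), (0.4 / 2.4)^2)
  expect_equal(fresnel_reflectance(1, 1.4, 0), 1 / 36, tolerance = 1e-12)
  # critical angle for 1.4 -> 1.0 is ~45.6 deg; beyond it R = 1
  expect_equal(fresnel_reflectance(1.4, 1, 60 * pi / 180), 1)
  # continuity: R -> 1 from below approaching the critical angle
  thc <- asin(1 / 1.4)
  R_below <- fresnel_reflectance(1.4, 1, thc - 1e-4)
  expect_gt(R_below, 0.9)
  expect_lte(R_below, 1)
  # reciprocity for transmitted rays: R(n1 -> n2 at theta1) = R(n2 -> n1 at theta2)
  th1 <- 0.4
  th2 <- asin(1.0 * sin(th1) / 1.4)
  expect_equal(fresnel_reflectance(1, 1.4, th1),
               fresnel_reflectance(1.4, 1, th2), tolerance = 1e-12)
})

test_that("reflection decision is Bernoulli in the reflectance", {
  expect_identical(reflect_or_transmit(0.99, 0), "TRANSMIT")
  expect_identical(reflect_or_transmit(0.01, 1), "REFLECT")
  set.seed(105)
  frac <- mean(vapply(stats::runif(1e5),
                      function(x) reflect_or_transmit(x, 0.25) == "REFLECT",
                      logical(1)))
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
})

test_that("direction rotation preserves unit norm and the deflection cosine", {
  u <- c(0, 0, 1)
  expect_equal(rotate_direction(u, 0, 1.2), u)
  expect_equal(rotate_direction(u, pi / 2, 0), c(1, 0, 0))
  expect_error(rotate_direction(c(1, 1, 0), 0.3, 0.3), "unit")
  set.seed(106)
  for (i in 1:200) {
    v <- runit()
    th <- stats::runif(1, 0, pi)
    w <- rotate_direction(v, th, stats::runif(1, 0, 2 * pi))
    expect_lt(abs(sum(w^2) - 1), 1e-12)
    expect_equal(sum(v * w), cos(th), tolerance = 1e-9)
  }
  # mean deflection cosine after rotation equals g for HG draws
  set.seed(107)
  n <- 2e4
  u0 <- c(0.3, 0.5, sqrt(1 - 0.34))
  ct <- vapply(seq_len(n), function(i) {
    th <- sample_polar_hg(stats::runif(1), 0.9)
    sum(u0 * rotate_direction(u0, th, stats::runif(1, 0, 2 * pi)))
  }, numeric(1))
  expect_lt(abs(mean(ct) - 0.9), 3 * stats::sd(ct) / sqrt(n))
})
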