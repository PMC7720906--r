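# Small, fast fixtures used across the suite.  Everything is generated in
# code; no data files.

# A thin absorbing slab in which photon paths are short (tens of steps):
# cheap enough for scalar-oracle replay and repeated-seed studies.
thin_slab_config <- function(photons = 500, seed = 42, mu_s = 5, mu_a = 0.5,
                             g = 0.7, n = 1.3, rho_R_total = 0,
                             rho_F_total = 0, max_iterations = 1e5,
                             thickness = 2, half = 5) {
  grid <- emission_grid()
  w <- grid$wavelength_nm[-1]
  cdfR <- if (rho_R_total > 0)
    build_conversion_cdf(mc_spectrum(w, rep(1, length(w))),
                         rho_R_total / length(w))
  cdfF <- if (rho_F_total > 0)
    build_conversion_cdf(mc_spectrum(w, rep(1, length(w))),
                         rho_F_total / length(w))
  m <- mc_material(1L, mu_s = mu_s, g = g, n = n, mu_a = mu_a,
                   rho_R = cdfR, rho_F = cdfF)
  run_config(layered_geometry(c(0, thickness), 1L, half), list(m),
             grid = grid, source = source_spec(), detector = detector_spec(),
             photons = photons, seed = seed,
             max_iterations = max_iterations)
}

# deterministic uniform stream for driving the pure samplers
make_stream <- function(seed = 1) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

# random unit vector (for geometry ray tests)
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
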