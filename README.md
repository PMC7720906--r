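# ramanmc

Monte Carlo simulation of spectroscopic light transport in turbid,
tissue-like media, with Raman sensing-depth metrology for fiber-probe
spectroscopy.

Label-free Raman spectroscopy is attractive for surgical guidance and
targeted biopsy, but its conversion rates are tiny and its measurements
integrate over an unknown depth range. Knowing *where* the detected Raman
signal was generated — the sensing depth of a given probe in a given tissue
— is essential for interpreting measurements against layer-resolved
pathology. `ramanmc` answers that question by simulation: it propagates
individual photons through layered slabs or voxel label volumes while four
interaction mechanisms compete along every path:

* **elastic scattering** — exponential free paths at rate μs(λ),
  Henyey–Greenstein deflection with anisotropy g(λ);
* **absorption** — per-segment Russian roulette with Beer–Lambert
  probability 1 − e^(−μa·l) (photons are indivisible particles, no packet
  weights);
* **fluorescence** — absorbed photons re-emit isotropically with total
  probability ρF, at a wavelength drawn from a tabulated conversion CDF;
* **Raman (Stokes) scattering** — at each collision site one uniform
  variate is compared against the cumulative wavelength-indexed conversion
  probabilities ρR(λ); a shifted photon continues at its new wavelength
  with re-fetched optical properties, and the conversion depth is recorded.

Boundaries use unpolarized Fresnel reflectance and Snell refraction;
everything outside the medium is void, where photons fly straight (and may
re-enter concave structures). Dispersion follows the near-infrared
empirical laws μs(λ) = a₁λ^(−a₂), g(λ) = a₃ + a₄λ, n(λ) = a₅ + a₆λ, with
tabulated μa(λ) and conversion spectra. The detection model is a handheld
annular fiber probe (inner d = 400 µm, outer d = 600 µm, 30° acceptance
in void) on the top surface.

The headline metric is the **sensing depth d_X**: the depth beyond which a
fraction X of detected Raman photons were generated — the (1 − X)
nearest-rank quantile of conversion depth, so d90 ≤ d75. Both the direct
estimator (recorded conversion depths of detected Raman photons) and an
exact conditional-expectation estimator (every accepted trajectory
contributes each of its collision-site depths with weight ρ(1−ρ)^(k−1);
valid for wavelength-flat media and indispensable at realistic rates
ρ ~ 10⁻⁶) are provided, with cluster-bootstrap confidence intervals.

The compiled event-loop engine (~10⁷ collision steps per second per core)
is paired with a scalar R reference implementation that replays the
engine's recorded random-variate stream and must reproduce its photon
records byte-identically — the package's engine-correctness contract.

## Worked example

75 % Raman sensing depth of the annular probe on a semi-infinite medium
(μa = 0.001 mm⁻¹, μs′ = 1 mm⁻¹, g = 0.9, n = 1.4) at a per-wavelength
Raman conversion rate of 10⁻³:

```r
library(ramanmc)
depth_study(mu_a_mm = 0.001, mu_s_prime_mm = 1, rho_R = 1e-3,
            photons = 2e5, seed = 42)
#>   mu_a_mm mu_s_prime_mm rho_R   d75_um  d90_um d75_ci_lo d75_ci_hi n_detected
#> 1   0.001             1 0.001 130.5414 51.3889  120.9931  138.8115        545
```

75 % of the detected Raman signal was generated deeper than ~131 µm
(95 % bootstrap CI 121–139 µm from 545 detected trajectories); 90 % was
generated deeper than ~51 µm. Raising the conversion rate, the scattering
or the absorption all pull the sensing depth toward the surface.

End-to-end spectroscopy on a synthetic PDMS-like phantom — simulate,
collect through the probe, remove the fluorescence background with a
rolling-ball baseline, SNV-normalize, and read off the Raman peaks:

```r
fx  <- make_phantom("I", rho_R_total = 0.05, rho_F_total = 0.3)
cfg <- run_config(fx$geometry, fx$materials, grid = fx$grid,
                  source = fx$source, detector = fx$detector,
                  photons = 4e5, seed = 1)
res <- run_simulation(cfg)
res
#> <mc_result> launched 4e+05 | absorbed 270246 | escaped 129754 | cap 0 | kept 527

spec <- bin_spectrum(res$records, fx$detector, fx$grid, launched = 4e5)
v <- spec$counts
r <- snv_normalize(v - rolling_ball_baseline(v, 5))
peaks <- which(r > c(-Inf, r[-100]) & r >= c(r[-1], -Inf) & r > 1)
round(spec$wavelength_nm[peaks], 1)
#> [1] 814.9 832.2 883.9 901.2
```

The four recovered peak wavelengths are exactly the four synthetic
Lorentzian lines the phantom generator placed (re-emission bins 5, 19, 61,
75). `make_phantom("III")` builds the two-layer version (913-µm PDMS-like
film over a nylon-like substrate), whose detected spectrum shows the
top-layer peaks plus attenuated substrate peaks.

## Command line

A thin CLI over the same functions ships in `inst/cli/ramanmc.R`:

```sh
Rscript ramanmc.R make-fixture --which I --out fixtures/phantomI
Rscript ramanmc.R simulate     --config fixtures/phantomI/config.json --out out/
Rscript ramanmc.R depth-study  --config study.json --out depths.csv
Rscript ramanmc.R postprocess  --in out/detected_spectrum.csv --out proc.csv \
                               --rolling-ball 5 --snv
```

Runs are reproducible from their manifest (config hash + seed);
`depth-study --resume` skips completed grid points byte-identically.

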