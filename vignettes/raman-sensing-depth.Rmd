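---
title: "Spectroscopic Monte Carlo transport and Raman sensing-depth metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic Monte Carlo transport and Raman sensing-depth metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ramanmc` simulates light transport in turbid, tissue-like media with four
competing photon-matter interactions: elastic scattering, absorption,
fluorescence and Raman (inelastic) scattering.  Photons are indivisible
particles — there is no packet weight.  Along each trajectory:

* **Elastic scattering.** Free paths are exponential with rate
  $\mu_s$ (mm$^{-1}$): $l = -\ln(1-\xi)/\mu_s$.  At each collision site the
  direction is deflected by the Henyey–Greenstein phase function with
  anisotropy $g$ (inverse-CDF sampling; the isotropic limit
  $\cos\theta = 2\xi - 1$ is used for $|g| < 10^{-6}$, where the closed form
  is singular) and a uniform azimuth.
* **Absorption.** A Russian-roulette test per traveled segment: the photon
  is annihilated with the Beer–Lambert probability $1 - e^{-\mu_a l}$ over
  the actually traveled (possibly boundary-truncated) length.  This is the
  analog equivalent of continuous attenuation and reproduces classical
  semi-infinite reflectance results (see *Validation* below).
* **Fluorescence.** An absorbed photon re-emits with total probability
  $\rho_F$ (the final value of the fluorescence conversion CDF), at a
  wavelength drawn from that CDF — the emission grid includes the source
  wavelength, so re-emission at the excitation line is representable — and
  in an isotropic direction.
* **Raman scattering.** Once per collision site, one uniform variate is
  compared against the material's cumulative, wavelength-indexed conversion
  probabilities; if it falls below the total, the photon shifts to the
  shortest qualifying wavelength, its optical properties are re-fetched at
  the new wavelength, and the conversion depth is recorded.

Boundaries use unpolarized Fresnel reflectance (average of the s and p
coefficients, with total internal reflection beyond the critical angle) and
Snell refraction.  The medium is embedded in void: outside all structures,
photons fly in straight lines, and may re-enter concave geometries.
Geometries are layered slabs (closed-form plane intersections) or voxel
label volumes (exact 3-D DDA traversal); both support the same transport
contract, and a homogeneous slab transports identically in either
representation (tested).

Wavelength-dependent properties follow the empirical dispersion laws of the
near-infrared window: $\mu_s(\lambda) = a_1 \lambda^{-a_2}$,
$g(\lambda) = a_3 + a_4\lambda$, $n(\lambda) = a_5 + a_6\lambda$, with
tabulated $\mu_a(\lambda)$ and conversion spectra.  The emission grid is
100 wavelengths equally spaced over 810–932 nm, plus the 785-nm excitation
line as grid point 1.

## Event-loop ordering

The per-photon loop is *hop–drop–spin*: sample a free path, trace it along
the current direction (truncating at the first material interface), apply
the absorption roulette over the traveled length, and only then — at a
completed collision site — deflect the direction.  An alternative ordering
that re-samples the deflection before every segment (including immediately
after entering the medium and after every boundary reflection) injects
phase-function deflections at points where no scattering event physically
occurred.  The difference is not cosmetic: for a semi-infinite isotropic
medium with single-scattering albedo 0.9, the deflect-first ordering gives a
diffuse reflectance of 0.76 where the exact value is
$1 - H(1)\sqrt{1-\omega} \approx 0.42$ (Chandrasekhar's H-function), which
the collision-site ordering reproduces.  `ramanmc` therefore deflects at
collision sites only.

For the same reason, Raman conversion opportunities exist at collision
sites, not at entry or boundary touch points: a conversion at the entry
surface with zero material traversed is unphysical and would pin the
90% sensing depth to zero whenever the per-collision conversion probability
is appreciable.

When a step is truncated at an interface, a **new full step** is sampled in
the next medium rather than rescaling the residual path; for exponential
free paths the two are statistically identical (memorylessness), and the
fresh draw correctly re-scales to the new medium's $\mu_s$.

## Conversion rates and their units

Conversion-rate spectra are proportional to the material's re-emission
spectra; the proportionality constant is a free parameter of any such model
(absolute Raman cross sections for these materials are not established).
The CDFs are built by discrete summation over the emission grid: the grid
is a set of discrete emission lines compared against one uniform variate,
so only cumulative mass per grid point is meaningful.

For the homogeneous depth-study media, `make_depth_medium(rho_R = ...)`
interprets its rate argument as the **per-wavelength** flat rate: the total
per-collision conversion probability is $100\,\rho_R$.  The package adopts
this reading because it is the only one under which the conversion rate
influences the sensing depth across the studied range
$\rho_R \in [10^{-6}, 10^{-3}]$: detected trajectories make tens to a few
hundred collisions, so first-shift depletion is only appreciable when the
per-collision total reaches $\sim 10^{-2}$–$10^{-1}$.  Were the quoted
numbers per-collision totals, the depth-versus-rate curves would be flat —
and the measured variation (a 75% sensing depth moving from ~130 µm at
$\rho_R = 10^{-3}$ to ~310 µm at $10^{-6}$, ratio 0.42) would be
impossible.

## The fiber-probe detection model

The handheld probe is modeled as an annular collection aperture on the top
surface — inner diameter 400 µm (the illumination port), outer diameter
600 µm — with a 30° acceptance half-angle measured in void, after
refraction at the exit surface, where detection physically happens.  A
full-disk reading (inner radius 0) is available via `detector_spec()`
because the geometry's verbal description admits both.  Sensitivity of the
75% sensing depth to this choice is substantial (at
$\mu_s' = 0.5$ mm$^{-1}$: 397 µm for the annulus, 268 µm for the full
disk, 612 µm for a hypothetical 0.5–1.0 mm annulus), which makes the probe
reading the dominant systematic when comparing sensing depths across
implementations; the source–detector offset, as in spatially offset Raman
spectroscopy, largely sets the depth scale.

## Sensing-depth metrology

The sensing depth $d_X$ is the depth *beyond which* a fraction $X$ of
detected Raman photons were generated: the $(1-X)$ empirical quantile of
the conversion-depth sample, nearest-rank rule.  Under this convention
$d_{90} \le d_{75}$.  Both the direct estimator (recorded first-shift
depths of detected Raman photons) and a conditional-expectation estimator
are provided (`raman_depth_sample()`).

The conditional-expectation ("expected") estimator exploits an exact
structural property of the depth-study media: every optical property is
flat across the emission grid, so a photon's trajectory is rigorously
independent of the Raman-shift lottery.  The expectation over the shift
draws can therefore be taken analytically — the $k$-th collision site of an
*accepted* trajectory contributes its depth with weight
$\rho (1-\rho)^{k-1}$, the probability that the first shift happens exactly
there.  This computes the same distribution as the direct estimator (the
two agree within bootstrap error at rates where both are well powered;
tested), but every accepted trajectory contributes.  At realistic rates the
difference is decisive: with the annular probe, the direct estimator
detects on the order of one Raman photon per $10^{7}$ launched at
$\rho_R = 10^{-6}$, while the expected estimator extracts thousands of
effective trajectories from $10^{6}$ launched photons.  It is *not* an
approximation, and it is not a scaling or perturbation reuse of a baseline
run — every reported number still comes from a fresh, full transport
simulation at the stated parameters.  Confidence intervals use a cluster
bootstrap over trajectories, since the weights within one trajectory are
dependent.  In media whose spectra are not wavelength-flat the equivalence
does not hold and the direct estimator should be used.

## Synthetic phantoms

`make_phantom()` builds in-silico replicas of the validation phantoms: 10-mm
single layers of PDMS-like and nylon-like material, and a two-layer phantom
with a 913-µm PDMS-like film over a 10-mm nylon-like substrate.  Their
dispersion curves are smooth synthetic interpolants pinned to the measured
endpoint values over 500–1000 nm (PDMS: $\mu_a$ 0.11→0.075 mm$^{-1}$
linear, $\mu_s'$ 0.65→0.45 mm$^{-1}$ power law; nylon: 0.02→0.01 and
1.05→0.25), with $g = 0.9$ and $n = 1.4$ — stand-ins for the measured
curves, not digitizations.  Raman spectra are sums of narrow Lorentzians at
profile-specific positions drawn from interleaved slots at least 3 bins
apart, so layered simulations can attribute every peak to a layer;
fluorescence is one broad hump per material.  The conversion-probability
scales are documented fixture values with no claim of physical
absoluteness (`rho_R_total`, `rho_F_total`).

What the generator does *not* emulate: measured instrument response and
shot-to-shot system drift, true PDMS/nylon peak wavenumbers and relative
intensities, surface roughness and curvature, and container/boundary
artifacts.  Passing the end-to-end tests therefore demonstrates that the
transport, detection and spectral post-processing chain is self-consistent
— not that any specific laboratory spectrum would be reproduced line for
line.

## Numerical choices

* RNG: xoshiro256++ with splitmix64 seeding; one independent, deterministic
  substream per batch, so results are exactly reproducible for a given
  (seed, photons, batches) and resumable runs are byte-identical.
* Every sampler is a pure function of explicit uniforms; the compiled
  engine can record or replay its variate stream, and a scalar R reference
  implementation (`propagate_photon()`) reproduces its records
  *byte-identically* on a recorded stream — the engine-correctness
  contract.
* Interface hits are searched beyond a 1 nm exclusion zone; after any
  boundary event the photon is nudged 0.1 nm along its new direction, so
  positions never sit exactly on a plane.  Voxels own half-open cubes.
* Out-of-grid wavelength queries clamp to end values; all simulated shifts
  stay inside the declared band by construction.
* The iteration cap defaults to $10^5$ per photon; capped photons are
  counted, reported, and warned about (shipped test configurations stay
  well below 0.1%).
* Rolling-ball baseline: 1-D grayscale opening (moving minimum then moving
  maximum) with a flat window of $2w+1$ bins, edge-clipped; $w$ is a
  required parameter, and ~10× the widest expected peak FWHM (in bins) is a
  sensible default on the 100-bin grid.  SNV uses the sample ($N-1$)
  standard deviation.
* The semi-infinite depth-study medium is realized as its exact layered
  representation (a 2 × 2 × 2 cm slab with analytic boundary planes); the
  256³ voxel rasterization of the same slab is available and transports
  identically for this homogeneous medium, at higher traversal cost.

## Validation

Beyond unit tests of every sampler against closed forms, the engine is
validated against independent references: diffuse reflectance of a
semi-infinite isotropic medium with albedo 0.9 matches the H-function value
($0.4155$ measured vs $\approx 0.419$); an independently coded
Henyey–Greenstein oracle at $g = 0.75$ agrees to Monte Carlo error; the
similarity-equivalent forward-peaked medium ($\mu_s' $ matched) agrees with
its isotropic counterpart; and the Kolmogorov–Smirnov, mean-cosine and
Fresnel identities hold at their stated tolerances.

## Problem sizes

Simulation sizes shipped in the test suite and the acceptance script are
the package's reproducibility choices: sensing-depth points use
$1.2\times10^5$–$10^6$ photons in tests and $1.5$–$2.5\times10^6$ in the
acceptance script, which yield 3 000–8 000 effective detected trajectories
per point under the expected estimator, i.e. bootstrap CIs of a few percent
on $d_{75}$.  The original study used $6\times10^7$ photons per grid point
with the direct estimator.

## Known limitations

* Polarization, time-of-flight, stimulated/nonlinear Raman, and
  patterned-illumination or camera-based detection are out of scope (the
  pinhole-camera parameters are parsed for configuration compatibility but
  not simulated).
* Conversion CDFs are independent of the incident wavelength (one CDF per
  material), which is adequate for single-excitation studies.
* The probe-geometry reading (annulus vs disk; acceptance-angle reference
  frame) is the dominant systematic for absolute sensing depths; published
  values can differ by tens of percent between defensible readings, and
  comparisons across implementations should fix the reading explicitly.
* Double Raman shifts are permitted (their probability is negligible at
  realistic rates); fluorescence re-absorption cascades are simulated
  naturally by the event loop.
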