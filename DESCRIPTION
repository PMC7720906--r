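Package: ramanmc
Title: Spectroscopic Monte Carlo Simulation of Raman and Fluorescence Light
    Transport in Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A Monte Carlo photon-transport simulator for turbid (tissue-like)
    media in which elastic scattering, absorption, fluorescence and Raman
    (inelastic) scattering compete along each photon path.  Photons are
    propagated as indivisible particles through layered slabs or voxelized
    label volumes embedded in void, with Henyey-Greenstein angular sampling,
    Russian-roulette absorption, Fresnel boundary handling and
    wavelength-shifting via tabulated conversion cumulative distribution
    functions.  Includes a fiber-probe detection model (annular collection
    aperture with an acceptance angle), spectral post-processing (rolling-ball
    baseline removal, standard-normal-variate normalization), tissue-phantom
    fixture generators, and Raman sensing-depth metrology (cumulative
    conversion-depth curves and their quantile summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
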