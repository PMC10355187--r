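Package: oceanhsrl
Title: Triple-Field-of-View High-Spectral-Resolution Oceanic Lidar Simulation and Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and iterative inversion of multi-field-of-view
    high-spectral-resolution oceanic lidar measurements. Provides Fournier-Forand
    particle optics driven by a power-law particle size distribution, a semianalytic
    Monte Carlo multiple-scattering simulator of range-resolved molecular and combined
    lidar channels, a fast quasi-single-scattering analytic forward model, and a
    Gauss-Newton retrieval of vertical profiles of seawater absorption, scattering,
    and particle-size-distribution slope, with derived products (diffuse attenuation,
    particulate backscattering, lidar ratio, single-scattering albedo).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
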