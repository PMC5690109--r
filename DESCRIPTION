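Package: kvbeam
Title: Empirical Kilovoltage X-Ray Source Modeling and Kerma-Approximation
    Dose Computation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes a superficial (kV) radiotherapy X-ray source from
    clinic-feasible measurements and computes relative dose in voxelized
    water phantoms.  Provides a parametric tungsten-anode spectrum model
    with half-value-layer (HVL) tuning of the inherent filtration,
    three-point semilogarithmic HVL determination from transmission series,
    an effective point source built from relative in-air dose scans with
    spatially varying spectra (heel effect), a Monte Carlo photon transport
    engine under the kerma approximation (photoelectric, coherent and
    incoherent scattering; no electron transport), and percentage
    depth-dose / profile analysis with percent-difference statistics.
    Bundles NIST-provenance photon attenuation and energy-absorption
    tables, and synthetic-measurement generators so the full pipeline is
    testable without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
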