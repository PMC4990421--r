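Package: mapfit
Title: Multi-Resolution Flexible Fitting of Molecular Models into Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flexible fitting of coarse-grained molecular models into 3-D
    cryo-EM density maps by molecular dynamics biased with a map-derived
    potential (MDFF), including the cascade (cMDFF) and resolution-exchange
    (ReMDFF) protocols that fit through a ladder of Gaussian-blurred maps of
    decreasing blur half-width. Provides MRC/CCP4 map input and output,
    Gaussian blurring and B-factor sharpening in Fourier space, a
    structure-based coarse-grained dynamics engine with Langevin integration,
    Metropolis resolution-exchange sampling, and map-model validation tools:
    global and local cross-correlation, Fourier shell correlation and its
    resolution-range integral, half-map cross-validation, RMSF profiles,
    RMSF-derived B-factors, sharpening scans and Guinier analysis. A
    synthetic-fixture generator produces toy two-domain structures, displaced
    conformer pairs, simulated maps, half-map pairs and spatially varying
    local-resolution volumes for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
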