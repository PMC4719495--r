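Package: alternanspop
Title: Population-of-Models Analysis of Repolarization Alternans in Human
    Ventricular Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates populations of biophysically detailed human ventricular
    epicardial action potential models (O'Hara-Rudy dynamic model) with
    cell-to-cell variability in ionic conductances and permeabilities sampled
    by Latin Hypercube design. Provides steady-state pacing and dynamic
    restitution protocols, action potential and calcium transient biomarkers,
    calibration of the model population against activation recovery interval
    (ARI) envelopes, detection and classification of repolarization alternans
    into Eye-type (closed restitution bifurcation) and Fork-type (open
    bifurcation) phenotypes, per-beat sarcoplasmic reticulum and sarcolemmal
    calcium balance metrics, action potential clamp experiments, and in silico
    interventions on L-type calcium current kinetics and sodium-calcium
    exchanger block. Includes a synthetic in vivo module that generates ARI
    calibration envelopes and toy unipolar electrograms with the
    derivative-rule ARI extractor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
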