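Package: saltadyn
Title: Quantitative Analysis of Saltatory Cell Migration, Energetics and
    Autophagic Flux from Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of time-lapse imaging of
    saltatorily migrating cells such as neuroblasts of the rostral migratory
    stream. Segments instantaneous-speed traces into migratory and
    stationary phases, computes migration metrics (net displacement,
    percent time migratory, migratory-phase speed), quantifies ratiometric
    biosensor signals (PercevalHR ATP/ADP, pHRed pH) including a per-phase
    "charge" statistic (baseline-relative area under the ratio curve divided
    by phase duration), detects and classifies tandem RFP-GFP-LC3 puncta
    for autophagic-flux readouts, builds kymographs, profiles leading-process
    fluorescence in fixed-width arc-length bins after rolling-ball background
    subtraction, and runs the associated statistical comparisons
    (pooled/Welch t-tests with F-test variance screening, one-way ANOVA with
    Fisher LSD post hoc). A synthetic-data generator with exported ground
    truth makes every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
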