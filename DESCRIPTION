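Package: mvamep
Title: Multilevel Kinetic Modelling of Terpenoid Precursor Biosynthesis in Rice
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variant-specific kinetic models of isopentenyl diphosphate (IPP)
    and dimethylallyl diphosphate (DMAPP) biosynthesis through the cytosolic
    mevalonate (MVA) pathway, the plastidic methylerythritol 4-phosphate (MEP)
    pathway, and three engineered plastid-targeted ectopic MVA pathway variants
    in rice. Provides a saturating rate-law formalism, ODE assembly with
    analytic Jacobians, steady-state solving and eigenvalue stability
    classification, logarithmic parameter sensitivities with Euclidean-norm
    aggregation, minimal-intervention Vmax stabilization scans, hormone
    coupling through power-law or saturating multipliers with detection-limit
    handling, forward stepwise phenotype regression with AICc, and a fully
    deterministic synthetic-data generator for end-to-end testing of the
    multilevel pipeline from gene expression to macroscopic phenotype.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, deSolve, jsonlite, xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
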