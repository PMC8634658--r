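Package: gemfba
Title: Constraint-Based Analysis of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of genome-scale metabolic
    models (GEMs): reading and writing SBML Level 3 Version 1 files with the
    'fbc' (version 2) and 'groups' extensions, converting reaction tables in
    CSV form into models, flux balance analysis (FBA), flux variability
    analysis (FVA) including a loopless variant based on a nullspace
    mixed-integer formulation, model quality auditing (elemental and charge
    balance, dead-end and orphan metabolites, stoichiometric consistency,
    biomass molecular weight, energy-generating-cycle detection, annotation
    coverage), growth simulation under defined media with aerobic and
    anaerobic switches and carbon-source scans, and production phenotyping
    (amino-acid production economics, growth-product trade-off curves,
    knock-out experiments, and pinned-reaction extraction). Includes
    deterministic generators for small synthetic models with analytically
    known optima and plantable defects so every pipeline stage can be
    verified offline. The linear and mixed-integer programming machinery
    (bounded-variable simplex with Bland's rule, branch-and-bound) is
    implemented in pure R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
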