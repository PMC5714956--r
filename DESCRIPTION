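Package: confsel
Title: NMR Tests of Conformational Selection in Peptide-Domain Binding
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a disordered peptide binds its partner
    domain by conformational selection, using solution-NMR observables.
    Implements secondary-chemical-shift and secondary-structure-propensity
    (SSP) analysis, chemical shift index (CSI), Karplus-based helix
    populations from 3J(HN-HA) couplings, chemical shift perturbation (CSP)
    mapping, residual dipolar coupling (RDC) back-calculation with
    SVD-based Saupe alignment-tensor fitting (Q factor, Pearson r,
    normalized scalar product between tensors), rigid-helix conformer
    sampling with RMSD-based clustering and interhelical-angle filtering,
    and a synthetic-data generator so the whole pipeline is testable
    without external downloads. Includes multi-model PDB coordinate I/O
    and a minimal NMR-STAR chemical-shift reader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
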