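Package: tetflux
Title: Flux-Balance Modeling and Structure Selection for TET-Mediated
    Cytosine Demethylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A linear compartment model of cytosine methylation and active
    demethylation in DNA, covering the 5-mdC / 5-hmdC / 5-fdC / 5-cadC
    oxidation cascade driven by the TET dioxygenases together with the
    AID deamination branch and TDG/SMUG1-initiated base-excision repair.
    Provides closed-form and numerical steady states, eigenvalue stability
    analysis, non-negative least-squares estimation of enzyme-substrate
    rate coefficients from steady-state flux balances across cell lines,
    exhaustive enumeration of the 343 candidate assignments of TET1/2/3 to
    the three oxidation reactions, and leave-one-cell-line-out
    cross-validation to rank those model structures.  Includes a synthetic
    cell-line data generator for end-to-end validation and readers/writers
    for the tabular transcript-level and modification-level inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
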