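Package: mscbend
Title: Continuum Mechanics of Hydrophobic Mismatch and Local Bending in
    Mechanosensitive Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale continuum analysis of how protein-lipid hydrophobic
    mismatch and local membrane bending jointly modulate the bacterial
    mechanosensitive channel MscL.  Provides mean-field lateral pressure
    profiles for bilayers of different acyl-chain length, a small
    axisymmetric linear-elastic finite-element solver for a channel-shaped
    inclusion embedded in a three-layer laminate membrane, a closed-form
    gating free-energy model combining mismatch and Helfrich-type bending
    terms, and a calculator linking asymmetric lysolipid insertion,
    monolayer area difference and induced local curvature.  Includes
    scenario fixtures, robustness sweeps and report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
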