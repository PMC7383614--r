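Package: nacscreen
Title: Near-Attack-Conformation Screening for Enantioselective Epoxide Hydrolase Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric near-attack-conformation (NAC) analysis of
    enzyme-substrate conformational ensembles for predicting the
    enantioselectivity of limonene epoxide hydrolase variants acting on
    meso-epoxides. Reads multi-model PDB and XYZ trajectory files, binds
    catalytic atom roles, classifies every frame as proRR-reactive,
    proSS-reactive or non-reactive against configurable angle/distance
    windows, estimates replica-averaged NAC frequencies, predicts
    enantiomeric excess from the two attack-mode frequencies, runs a
    stepwise MD-budget elimination cascade over design libraries, ranks
    surviving designs, and triages designs by active-site cavity volume
    change.  Includes a stochastic generator of replica-structured
    conformational ensembles with known ground-truth occupancies, and
    Michaelis-Menten utilities for the experimental side of a design
    campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
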