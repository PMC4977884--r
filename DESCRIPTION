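Package: coremetab
Title: Core Metabolic Models of Central Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis of core metabolic models (CMMs) of
    bacterial central metabolism, fermentation and the electron transport
    chain. From a curated core model template (compounds, mass- and
    charge-balanced reactions, gene-protein-reaction rules, electron
    transport variants with explicit proton-translocation stoichiometry,
    and a library of minimal media) and a genome's functional-role
    annotations, the package builds a reduced stoichiometric model,
    predicts ATP yields and biomass-precursor producibility by flux
    balance analysis, finds cardinality-minimal gapfilling sets,
    classifies energy pathways and respiration types with Boolean rules,
    analyses pairwise pathway co-occurrence across genome collections,
    and collapses phylogenetic trees for pathway visualisation. A
    synthetic annotation generator with known ground truth supports
    testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ape,
    phangorn,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
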