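Package: paceburst
Title: Quantification of Synaptically Driven Spike Patterning in Dopaminergic Pacemaker Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for patch-clamp and imaging studies of
    glutamatergic control of substantia nigra dopaminergic pacemaker
    neurons. Provides voltage-clamp EPSC quantification (paired-pulse
    ratio, AMPA:NMDA ratio, current-voltage relations, drug-effect
    percent change), subcellular optogenetic (sCRACM) input mapping
    registered to dendritic path distance, current-clamp spike analysis
    (dV/dt threshold detection, phase plots, phase-resolved evoked-spike
    comparison, pacemaker resetting, train following, soma-axon spike
    matching), line-scan calcium transient quantification (dF/F0 and
    transient area), the accompanying non-parametric statistical layer
    (exact Mann-Whitney and Wilcoxon tests with Holm-Bonferroni
    correction, quadratic fits with confidence bands), and a fully
    seeded synthetic-data generator that produces every input modality
    with known ground truth so each analysis stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
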