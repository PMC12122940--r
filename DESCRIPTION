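Package: dualspec
Title: Dual-Substrate Specificity Analysis for Protein Lysine
    Methyltransferases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of the dual H3K4/H3K36 substrate
    specificity of PR/SET-domain protein lysine methyltransferases such
    as PRDM9. Classifies molecular-dynamics trajectory frames as SN2
    transition-state-like from the lysine Nepsilon / AdoMet methyl
    carbon / sulfur geometry, computes peptide-enzyme residue contact
    fraction maps, quantifies SPOT specificity-scan peptide arrays
    (min-max normalization, replicate averaging, discrimination
    factors), fits shared-amplitude two-rate exponential methylation
    progress curves, and tests substrate enrichment with Fisher's exact
    test. A synthetic-data generator with planted geometric and kinetic
    parameters makes the whole pipeline testable without raw
    trajectories, arrays or gel images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
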