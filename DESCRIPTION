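Package: SynIDPDesign
Title: Design and Verification of Synthetic Intrinsically Disordered
    Protein Solubility Tags
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational pipeline for discovering synthetic intrinsically
    disordered protein (SynIDP) solubility tags from repeat-motif gene
    libraries. Enumerates constrained PG-X4 hexapeptide repeat motifs,
    reverse-translates them into 72-nt oligonucleotides carrying a single
    junction-split SexAI site with minimal direct/inverted nucleotide
    repeats, simulates rolling-circle amplification with stochastic
    5-methylcytosine protection and methylation-blocked restriction
    digestion (geometric fragment-length law, size selection, methyl
    fraction optimization), verifies library content from sequencing reads
    by circular alignment and filtering, predicts solubility from sequence
    (Urry-scale hydropathy, Wilkinson-Harrison model, composition and mass
    reports), and analyses polymer small-angle scattering (Debye, rigid
    rod and polymer-excluded-volume form factors, Kratky classification,
    Porod exponents, chain-ensemble simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    pracma,
    minpack.lm,
    lhs,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
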