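Package: phrscan
Title: Photolyase Variant Analysis and UV Survival Genotype-Phenotype
    Correlation for Haloarchaea
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating DNA photolyase (phr2) gene variants to
    ultraviolet-radiation survival phenotypes in halophilic archaea.
    Identifies protein residues proximal to the bound DNA substrate and the
    FAD and 8-hydroxy-5-deazaflavin (HDF) cofactors on a reference
    photolyase crystal structure, maps those positions onto homologous
    photolyases by global alignment, classifies cross-strain substitutions,
    models single-residue replacements and scores hydrogen-bond gain or
    loss by geometric criteria, summarises colony-count UV dose-response
    data into percent-survival and photoreactivation-benefit curves, builds
    neighbor-joining 16S rRNA trees, compares gene neighborhoods around the
    phr2 anchor, and correlates a photolyase-integrity score with survival
    rankings. Includes seed-deterministic synthetic-data generators with
    machine-readable ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    phangorn,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralPrediction, SequenceMatching, Phylogenetics,
    ComparativeGenomics, Survival
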