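Package: diazoscope
Title: Shotgun-Metagenomic Quantification and Profiling of Soil Diazotrophs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and taxonomically profiles nitrogen-fixing (diazotrophic)
    prokaryotes in shotgun soil metagenomes using nitrogenase structural genes
    (nifD/nifK and the vnf/anf alternatives) as markers. Marker reads are detected by
    translated homology search against a curated reference database, abundances are
    expressed as the ratio of nitrogenase RPKM to the summed RPKM of universal
    single-copy ribosomal protein genes, nifH-only (pseudo-nifH) signals are flagged
    via the expected 3:5:5 nifH:nifD:nifK read proportion, samples are curated for
    16S rRNA evidence of Lactobacillales or chloroplast contamination and merged by
    sub-kilometre geographic clustering, and surviving nifD/K reads are taxonomically
    annotated by phylogenetic placement with confidence-weighted LCA. Beta-diversity
    statistics operate on placement mass: weighted UniFrac averaged over NifD and
    NifK, two-dimensional NMDS, PERMANOVA by label permutation, pairwise
    Brunner-Munzel tests with Bonferroni correction, and Spearman correlation. A
    synthetic-metagenome generator with known ground truth (log-normal communities,
    GC-biased fragment sampling, pseudo-nifH and contaminant taxa, sub-kilometre
    sampling replicates) supports end-to-end validation, and an in-silico primer
    evaluator counts IUPAC-aware mismatches of nifH universal primers at
    alignment-defined binding sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    MASS,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phangorn,
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
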