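Package: lolkit
Title: Discovery and Characterisation of Bacterial Lipoprotein-Sorting
    (Lol) Homologs from Template Hit Lists and Outer-Membrane Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for finding and characterising remote
    homologs of the lipoprotein-sorting chaperones LolA and LolB in
    Bacteroidota. Detects candidate homologs by comparing per-protein
    structural-template hit lists at an E-value cutoff, classifies
    signal peptides (SPI / SPII lipobox) with a rule-based surrogate and
    flags surface-export (LES) lipoproteins, profiles sequence
    physico-chemistry (Eisenberg hydrophobicity, residue composition,
    Henderson-Hasselbalch net charge, hydrophobic-gradient direction),
    filters label-free proteomics tables on fold change and
    -10*log10(p) significance with localization and functional-category
    tallies, and builds cross-species presence/absence matrices from
    homology-search hits. Ships seeded synthetic-data generators with
    planted ground truth so every stage is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
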