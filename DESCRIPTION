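Package: foldbackr
Title: Simulation and Detection of DSB-Induced Foldback Inversions in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic simulator and analysis pipeline for inverted
    duplication (foldback inversion) chromosome rearrangements induced by a
    double-strand break near natural inverted repeats in budding yeast.
    Builds seeded synthetic reference genomes carrying the relevant sequence
    context (imperfect target inverted repeat, PAM-overlapping repeat, delta
    and PAU repeat families, a homeologous donor gene); simulates survivor
    genomes through foldback annealing, hairpin capping, dicentric formation,
    breakage and stabilization; generates paired-end reads with truth
    alignments; calls copy-number variants by binned log2 read-depth ratios
    against a split-parental empirical null with FDR control; reconstructs
    rearrangement junctions from discordant read pairs by greedy overlap
    assembly; and classifies survivors from in-silico PCR and
    efficiency-corrected qPCR evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
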