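Package: phagedyn
Title: Phage-Vibrio Population Genomics and Abundance Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for longitudinal phage-host population studies in the
    oyster pathogen Vibrio crassostreae and its lytic and temperate phages:
    pairwise intergenomic similarity and complete-linkage clustering into
    genus and species ranks, clade-diagnostic SNP scoring and ddPCR
    primer/probe candidate design, pangenome plasticity-region calling with
    rule-based mobile-genetic-element classification and cargo-density
    statistics (Kruskal-Wallis, Dunn post hoc, compact letter display),
    weighted gene repertoire relatedness (wGRR) for plasmid presence
    inference, droplet digital PCR Poisson quantification with geometric
    replicate summaries, and time-series analysis (autocorrelation,
    cross-correlation, Lomb-Scargle periodogram, GCV smoothing splines).
    A synthetic-data module generates clade-structured bacterial
    populations, phage genome families with controlled divergence, and
    log-normally noisy, LOQ-censored abundance series so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
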