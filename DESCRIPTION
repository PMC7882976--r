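Package: scavtrace
Title: Forensic Microbiology of Scavenging: Decay Biomarkers in Consumer Gut Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to distinguish predation from scavenging in consumer diet
    studies by coupling carcass-decomposition microbiology with molecular diet
    analysis. Identifies fresh- and decayed-tissue bacterial biomarkers from a
    time-series 16S amplicon experiment, matches them into consumer gut
    microbiomes by global-alignment percent identity, combines the matches
    with rule-based PCR/Sanger diet calls, and classifies individual consumers
    as likely carrion feeders. Includes a synthetic-data generator with ground
    truth for validation, and from-first-principles implementations of the
    community statistics used to characterise the microbiomes (Faith's
    phylogenetic diversity, Jaccard, Bray-Curtis and unweighted UniFrac
    distances, PERMANOVA, PERMDISP, presence-absence indicator-value analysis
    with Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
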