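Package: navdup
Title: Detecting Sodium Channel Gene Duplication from Genotyping, Crosses
    and qPCR Copy Number
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting a tandem duplication of the voltage-gated
    sodium channel (NaV/kdr) gene in Aedes aegypti from indirect molecular
    evidence.  Models haplotypes at the 1011 and 1016 sites plus the intron
    A/B marker, the allele-specific PCR masking that makes duplication
    carriers mimic heterozygotes, Hardy-Weinberg goodness-of-fit on
    six-category two-site molecular phenotypes with gene-counting/EM
    haplotype frequency estimation, Fisher exact tests of Mendelian cross
    segregation against single-copy and duplication hypotheses, per-specimen
    clone haplotype profiling (three-haplotype specimens as duplication
    evidence), and TaqMan delta-delta-CT relative copy number.  Includes
    seeded generators for synthetic populations, crosses, clone reads and
    qPCR plates, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
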