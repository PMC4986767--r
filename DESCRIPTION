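Package: lensmosaic
Title: Detection and Quantification of Low-Frequency Somatic Variants in
    Paired Deep-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting somatic mosaicism at allele fractions of a
    few percent from targeted-capture deep sequencing of paired tissue
    samples. Implements paired (case versus matched control) somatic variant
    calling with a one-sided Fisher exact test, genotype-based
    germline/somatic/LOH classification, an unpaired error-model screening
    mode, and a configurable multi-stage quality filter cascade (depth,
    per-strand support, control absence, frequency window, cross-sample
    recurrence, and read-evidence filters) with a complete per-call audit
    trail. Also provides droplet digital PCR quantification (two-channel
    droplet classification, Poisson copy-number estimation, and variant
    allele fraction), conversion of allele fractions into clonal patch size
    estimates for an epithelial monolayer, and a synthetic pileup and
    droplet simulator with recorded ground truth so that every stage of the
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
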