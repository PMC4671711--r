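Package: ffpeqc
Title: Quality Control and Artifact-Rate Estimation for FFPE Versus Frozen Exome Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing whole-exome sequencing libraries prepared from
    formalin-fixed paraffin-embedded (FFPE) tissue against matched fresh-frozen
    and blood libraries. Provides a deterministic paired-end read simulator that
    injects formalin-fixation artifacts (fragment shortening, template-level
    cytosine-deamination C>T/G>A alterations, soft-clipped overhangs) with exact
    truth records; plain-text SAM ingestion and quality-filtered pileups;
    library degradation metrics (insert-size distributions, mate-overlap
    double-sequencing, soft-clip fractions, mapping-status and target-coverage
    summaries); a two-pass estimator of background sequencing error rates and
    FFPE-induced base-alteration rates over the twelve substitution classes at
    homozygous sites; and LOD-based somatic-call concordance sweeps between
    matched call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    vcfR,
    IRanges,
    S4Vectors,
    BiocGenerics,
    methods,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
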