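Package: crisprselect
Title: CRISPR-Select Editing-Outcome Quantification and Cohort Mutation
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies CRISPR-Select editing outcomes from amplicon
    sequencing reads and computes the internally controlled Mut:WT*
    selection statistic, including the single-allele (intron-guide)
    assay variant. Also provides the cohort-level statistical toolkit
    used to interpret DNA-repair gene mutations in tumor sequencing
    studies: helicase-domain mutation status calls, loss-of-heterozygosity
    from allele-specific copy-number segments, cross-platform tumor
    mutation burden harmonization, region-restricted 96-channel
    mutational-signature refitting by nonnegative least squares,
    margin-aware mutual-exclusivity testing with a Poisson-binomial null,
    and Kaplan-Meier / log-rank / Cox survival analysis. A synthetic-data
    module simulates both editing experiments (FASTQ with known ground
    truth) and cohorts with planted statistical structure so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
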