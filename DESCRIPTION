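Package: admpatlas
Title: Tissue-Specific Age-Related DNA Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls age-related differentially methylated positions (aDMPs)
    per tissue by epigenome-wide linear modelling of beta values against
    chronological age under a dual effect-size (>= 2% per 10 years) and
    Bonferroni-significance (P_bonf <= 0.05) criterion; quantifies
    cross-tissue sharing and specificity of aDMPs at the CpG, CpG-island and
    gene level; runs power-control calling variants (effect-size-only and
    equal-N subsampling); computes functional-annotation enrichments (CpG
    island geometry, 15-state chromatin segmentations, EZH2 binding,
    nearest genes) as odds ratios with chi-squared tests; and simulates
    annotation-structured multi-tissue 450k-like methylomes with planted
    ground-truth age effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
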