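Package: kdrkit
Title: Knockdown-Resistance Genotyping and Insecticide Bioassay Association
    Analysis for Sand Fly Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype calling at voltage-gated sodium channel (Vgsc) codon
    1014 from dual allele-discrimination assay readouts or Sanger amplicon
    sequences, association statistics linking kdr genotype to insecticide
    bioassay outcome (contingency tables, Fisher and chi-square tests,
    odds ratios, continuity-corrected Wilson intervals, Marascuilo-McSweeney
    multiple proportion comparisons, Holm correction, Abbott control-mortality
    correction), diagnostic-marker evaluation (sensitivity, specificity,
    predictive values), per-site allele frequency monitoring with
    multi-allelic Hardy-Weinberg testing, and a synthetic-data generator
    emulating field bioassay collections of Phlebotomus argentipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
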