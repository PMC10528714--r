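Package: methmr
Title: Summary-Statistics Mendelian Randomization Screen for Methylation-Mediated Trait Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a summary-statistics causal-inference screen that
    identifies CpG methylation sites transmitting an exposure's effect to
    quantitative traits. Provides the SMR co-localization test and the HEIDI
    heterogeneity (pleiotropy-vs-linkage) test, GSMR-style multi-instrument
    Mendelian randomization with LD-aware generalized least squares and
    pleiotropy-outlier removal, greedy p-value LD clumping against a genotype
    reference panel, allele harmonization for two-sample comparisons, a
    two-stage discovery/replication pipeline with reverse-causation filtering
    and expression-mediation chaining, and a pathway-level rank correlation of
    absolute Z-scores. A block-LD synthetic-data generator with known ground
    truth supports end-to-end validation. Readers and writers are included for
    COJO ".ma" GWAS summary files, long-format QTL tables, GMT gene sets, and
    PLINK bed/bim/fam or TSV genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
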