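Package: ctmr
Title: Drug-Target Cis Mendelian Randomization with Correlated Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for drug-target mendelian randomization from GWAS summary
    statistics. Provides fixed-effects pooling of exposure GWAS with a
    direction-concordance filter, cis instrument selection around target genes
    with greedy LD pruning and instrument-strength diagnostics (variance
    explained, F-statistic), inverse-variance weighted causal estimation that
    accounts for correlation between variants with a multiplicative
    random-effects dispersion floor, Wald ratios, leave-one-out and
    multivariable extensions, approximate-Bayes-factor colocalization of two
    traits in a region, weighted genetic risk score transcriptome-wide
    association scans with gene-set over-representation, and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
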