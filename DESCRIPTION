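Package: polyGS
Title: Genomic Selection for Autopolyploid Crops with Allele Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in autopolyploid crops such as
    tetraploid potato and hexaploid sweetpotato. Builds dosage-aware genomic
    relationship matrices (VanRaden additive at arbitrary even ploidy, a
    full dosage-class model, pseudo-diploidized and digenic-dominance
    codings, and haplotype-sharing kinships from phased full-sib data), fits
    G-BLUP mixed models by restricted maximum likelihood with one or two
    genetic kernels, and estimates predictive ability by replicated
    cross-validation with Fisher-Z aggregation and one-way ANOVA model
    comparison. Includes a score-statistic forward search for QTL on a
    genetic-map grid with Q-BLUP and Q+G-BLUP prediction modes, narrow-sense
    heritability and rate-of-genetic-gain calculators, marker filtering by
    minor allele frequency and call rate, and a polysomic-inheritance
    simulator (hypergeometric gamete model with optional double reduction,
    depth-limited dosage calling) for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
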