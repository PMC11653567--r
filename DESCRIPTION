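Package: ssdominance
Title: Sex-Specific Dominance of Gene Expression from Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers sex-specific dominance of gene expression from RNA-seq
    count data of reciprocal crosses between homozygous lines. Provides
    negative-binomial generalized linear models with per-gene dispersion
    estimation for cross designs (sex, additive, dominance and
    parent-of-origin effects and their sex interactions), estimation of the
    dominance coefficient of the high-expression allele relative to the
    midparent, likelihood-ratio tests for sex-by-dominance interactions,
    two-step focal-transcript filtering, classification of dominance
    reversals, Storey q-values, major-axis regression of male versus female
    dominance, directional Kolmogorov-Smirnov and exact tests for
    sex-bias association, GO term over-representation, and a synthetic-data
    generator with known per-gene truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
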