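Package: bdrprs
Title: Pharmacogenetic Polygenic Risk Score for Bronchodilator Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of a pharmacogenetic polygenic risk
    score (PRS) for bronchodilator response (BDR) to albuterol in children
    with asthma. Selects scoring variants from GWAS summary statistics by
    p-value and PHRED-scaled CADD deleteriousness score, harmonizes VCF
    genotypes to effect-allele dosages, computes the weighted allele-dosage
    score and its per-standard-deviation standardization, and fits adjusted
    linear and logistic association models at continuous and
    threshold-defined outcomes. Includes a synthetic cohort generator whose
    allele frequencies and BDR noise distribution are numerically calibrated
    to published cohort summary statistics, so the full pipeline can be
    exercised and validated by injected-parameter recovery without access to
    restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
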