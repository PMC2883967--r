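Package: renaldx
Title: Discriminative Genomics of Chromophobe Renal Cell Carcinoma and
    Renal Oncocytoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for separating chromophobe renal cell
    carcinoma (chRCC) from renal oncocytoma using bulk microarray
    expression and SNP-array copy-number data: coefficient-of-variation
    probe filtering and complete-linkage clustering, two-class unpaired
    SAM-style differential expression with permutation false discovery
    rates, a nearest-shrunken-centroid (PAM) classifier with a
    cross-validated minimal-predictor selection rule, expression-derived
    regional cytogenetic inference (CGMA), run-length copy-number
    segment and recurrent-alteration calling, hypergeometric gene-set
    enrichment with DAG-conditional testing, and two-sided exact tests
    for marker contingency tables. Ships a synthetic-data generator that
    emulates the two-cohort study design (15+15 tumors, 12 normal kidney
    references, 6+8 SNP-array samples) with a truth ledger for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
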