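Package: tnfsigval
Title: Validation of Anti-TNF Response Gene-Expression Signatures by
    Partition Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to assess whether published gene-expression signatures
    predict response to TNF-blocking therapy in rheumatoid arthritis.
    Patients are clustered on signature-restricted expression profiles with
    k-means under Pearson dissimilarity, clusters are identified as the
    responder and non-responder groups, and sensitivity and specificity are
    scored with non-responders as the positive class. Includes array-level
    quality control (control-probe ROC AUC, inter-array correlation
    outliers, quantile normalisation), GMT gene-set input and output, EULAR
    DAS28 response classification, cohort summary statistics, a genome-wide
    Welch differential-expression screen with Bonferroni control, power
    calculations on the noncentral t distribution, and a synthetic-cohort
    generator emulating a 42-patient whole-blood exon-array study so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
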