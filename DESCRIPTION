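Package: pdxomics
Title: Transcriptomic Classification, Deconvolution Benchmarking, Variant
    Filtering and Growth Statistics for Patient-Derived Xenograft Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for patient-derived xenograft (PDX) cohort
    studies in oncology. Classifies tumor transcriptomes against a labeled
    reference cohort by Spearman-correlation k-nearest neighbors with
    leave-one-out cross-validated selection of k; benchmarks external
    bulk RNA-seq cell-type deconvolution output against marker-gene
    signature scores; applies population-frequency and dbSNP somatic
    variant filters with a Cancer Gene Census/COSMIC whitelist and a
    PDX-only recurrence filter; computes caliper-based tumor volumes with
    per-timepoint multiple t tests, exact Fisher take-rate tests and
    Kaplan-Meier/log-rank survival comparisons. Includes a deterministic
    synthetic-data generator so every stage is testable without access to
    patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
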