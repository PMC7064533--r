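Package: osteomir
Title: miRNA Prognostic Signature Analysis for Osteosarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prognostic microRNA biomarker analysis
    in osteosarcoma. Implements signed-average survival risk scoring with
    median dichotomization, hierarchical clustering of samples with
    perturbation-based reproducibility (R-index), a composite prognostic
    classification combining molecular risk groups with pathologic
    chemotherapy response, LS/KS permutation gene-set survival tests with
    random-gene-set controls, EASE-score pathway enrichment, DNA methylation
    M-value analysis (differential methylation and miRNA-CpG correlation),
    and a staged pharmacogenomic drug filter ranking candidate compounds by
    median IC50 against a reference chemotherapeutic. A synthetic cohort
    generator with planted proportional-hazards effects, methylation
    coupling and active drugs supports calibration and parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
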