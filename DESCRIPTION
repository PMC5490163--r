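Package: isown
Title: Somatic Mutation Identification Without Matched Normal Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies single nucleotide variants called from tumor-only
    sequencing into somatic mutations and germline polymorphisms when no
    matched normal tissue is available. Per-sample VCF call sets are
    quality-filtered, annotated against somatic-catalogue, polymorphism and
    functional-impact databases, collapsed into unique alleles carrying ten
    annotation-derived and cohort-intrinsic features (including a
    binomial-confidence-interval comparison of each variant's allele
    frequency with flanking common polymorphisms), pre-labeled by two
    deterministic rules, and classified by supervised learning (naive Bayes
    with mixed categorical/Gaussian likelihoods, random forest, boosted
    trees) selected by tenfold cross-validation. A self-contained cohort
    simulator generates reference genomes, per-sample VCFs, annotation
    tables and truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    ranger,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
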