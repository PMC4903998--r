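Package: pidtriage
Title: Gene-Panel Triage of Annotated Exome Variants for Primary
    Immunodeficiency Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reproducible prioritisation of candidate disease-causing
    variants in cohorts of patients with common variable immunodeficiency
    (CVID) and related primary immunodeficiencies (PIDs). From a
    multi-sample annotated VCF, a pedigree, and a PID gene panel, the
    package applies a call-quality filter, restricts to panel genes,
    excludes variants that are too common in the general population under
    zygosity-dependent thresholds, and gates on CADD deleteriousness
    scores against gene-specific mutation significance cutoffs. Surviving
    calls are grouped per patient and gene under monoallelic or biallelic
    hypotheses, compound heterozygotes are phased through parental
    genotypes, de novo events and familial segregation are annotated, and
    each candidate is assigned a reporting tier with machine-readable
    reasons. A seeded synthetic-cohort generator with planted causal and
    decoy variants makes every stage testable without access to protected
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
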