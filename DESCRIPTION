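Package: psalloc
Title: Case-Mix Classification and Allocation Guidelines for Home-Care Personal Support
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying home and community care patients by need for
    personal support services and for deriving evidence-based hour-allocation
    guidelines. Implements interRAI-derived clinical scales (ADL Short Scale,
    ADL Hierarchy, Cognitive Performance Scale, IADL Difficulty, Self-Reliance
    Index), a table-driven decision-tree classifier producing six ordered need
    groups, a variance-reduction recursive-partitioning engine with Bonferroni
    adjusted F-test splitting, construction of weekly billed-hours dependent
    variables from service logs, validation metrics (explained variance,
    coefficient of variation, group-mean ratios), percentile-based allocation
    guideline bands with a statutory-cap auditor, and a calibrated synthetic
    cohort generator so the full pipeline can be exercised without access to
    administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
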