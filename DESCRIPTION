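Package: cariesharm
Title: Three-Tiered Harmonization of Dental Caries Phenotypes Across Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing surface-level dental caries examination
    records across heterogeneous cohorts using a three-tiered phenotype
    strategy: binary case status, tooth-morbidity severity indices
    (DMFT/DMFS with all-cause missing teeth in the M component), and
    precision caries-pattern traits scored on five predefined clusters of
    permanent-dentition tooth surfaces.  Includes a validated odontogram
    data model (FDI notation, 128 index surfaces, third molars excluded),
    de-novo hierarchical re-derivation of surface clusters, consortium
    registry roll-ups, inverse-standard-error-weighted linear
    meta-regression of cohort-level cluster scores on mean age, GWAS power
    calculations based on the one-degree-of-freedom noncentral chi-square
    distribution, and a synthetic-cohort generator with cluster-structured
    susceptibility, age dependence, person-level frailty, and all-cause
    tooth loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mclust
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
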