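Package: txinjury
Title: Molecular Injury Archetypes and Outcomes in Kidney Transplant Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a molecular injury model for kidney transplant
    biopsies: pathogenesis-based transcript (PBT) set scores computed as mean
    log2 fold-change against nephrectomy controls, cross-validated binary
    molecular classifiers (low eGFR, proteinuria, fibrosis ci>1, atrophy
    ct>1), correlation PCA of the ten standardized injury inputs with
    deterministic component orientation, archetypal analysis with five
    injury archetypes (normal, AKI1, AKI2, mild CKD, CKDAKI), supplementary
    projection of failed-repair gene-set means onto the factor map, and
    biopsy-anchored death-censored survival analyses (Kaplan-Meier, Cox
    models with time-varying component effects, random survival forest
    variable importance). A synthetic cohort generator with known latent
    injury axes, donor-age and eGFR couplings, and hazard links makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ranger,
    glmnet,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
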