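Package: weanotype
Title: Piglet Fecal Enterotypes and Growth Across the Weaning Transition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis workflow for multi-farm piglet fecal 16S count data
    across the weaning transition. Provides OTU-table quality control,
    prevalence/abundance filtering, rarefaction and rank aggregation;
    alpha diversity, Jensen-Shannon and Bray-Curtis beta diversity with
    PERMANOVA and a dispersion-homogeneity test; enterotype discovery by
    deterministic k-medoids (PAM) with Calinski-Harabasz model selection,
    silhouette validation and longitudinal transition dynamics; the
    relative average daily gain (rADG) robustness phenotype with within-farm
    growth classes; nonparametric taxon-factor association tests including a
    two-step permutation procedure for the growth-by-age interaction; a
    best-subset linear rADG predictor with leave-one-farm-out validation;
    and a calibrated Dirichlet-multinomial synthetic cohort generator that
    emulates the compositional, enterotype, farm-effect and growth structure
    of a 16-farm weaning study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite
Config/testthat/edition: 3
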