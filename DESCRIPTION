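Package: heatgarden
Title: Common-Garden Analysis of Recurrent Marine Heatwave Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recurrent heat-stress responses of temperate
    octocorals measured in repeated common-garden thermotolerance assays.
    Implements necrosis-trajectory descriptors and impact classes, a PCA-based
    individual fitness proxy with Box-Cox normalisation, mixed-model variance
    partitioning of the year, population and individual components, Weir-Cockerham
    F_ST and DAPC-style clustering on microsatellite genotypes, standardized
    multilocus heterozygosity with a Monte-Carlo heterosis test, marine heatwave
    and heat-spike detection against a day-of-year percentile climatology, and
    Finlay-Wilkinson environmental-sensitivity slopes with a randomization null.
    A synthetic-data generator reproduces the statistical structure of the field
    design so the whole pipeline is testable without the deposited data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    car,
    emmeans,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
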