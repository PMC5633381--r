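Package: fluctLOH
Title: Classification and Fluctuation-Assay Rate Estimation of
    Loss-of-Heterozygosity Events in Diploid Yeast
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for marker-based loss-of-heterozygosity (LOH) assays in
    diploid yeast. Classifies 5-fluoroorotic-acid-resistant colonies into
    LOH classes (whole-chromosome loss, gene conversion, segmental LOH,
    complex events) from growth phenotypes on selective media, subclassifies
    complex events from PCR zygosity calls, estimates per-class LOH rates
    from fluctuation assays by the Lea-Coulson method of the median with
    order-statistic confidence intervals, and provides the accompanying
    inferential toolkit (exact and chi-square contingency tests, rate
    independence products with binomial bounds, rank and Welch tests, and
    pulsed-field gel band-fraction summaries). A forward Luria-Delbrueck
    culture simulator generates synthetic fluctuation data with the jackpot
    structure the estimators assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'markerMap.R'
    'genotype.R'
    'classify.R'
    'fluctLOH-package.R'
    'simulate.R'
    'io.R'
    'statTests.R'
    'rates.R'
    'pipeline.R'
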