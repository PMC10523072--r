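Package: floralsync
Title: Seasonal Sex Allocation, Mating Opportunity and Siring Success in
    Clonal Monoecious Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether seasonal adjustments of sex allocation in
    synchronously protogynous, monoecious clonal plants translate into
    realized siring success. Provides a synthetic-population simulator
    (clonal structure, microsatellite genotypes, daily floral phenology,
    spatially restricted mating with known paternity), multilocus
    genotype/lineage clustering for clone assignment, fractional paternity
    assignment from codominant markers, the pollen-transfer-opportunity
    index, siring-success aggregation, and seasonal trend models
    (penalized-spline mixed models with linear mixed-model comparisons),
    together with a file-based pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
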