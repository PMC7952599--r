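Package: servweb
Title: Robustness of Food Webs and the Ecosystem Services They Provide
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Attaches ecosystem-service nodes to directed food webs and
    quantifies how robust both the web and its services are to sequential
    species loss. Simulates bottom-up secondary-extinction cascades under
    topological, threat-based and service-centred removal sequences
    (including a personalized-PageRank ranking of supporting species),
    computes area-under-curve robustness for the food web, for services in
    aggregate and for individual services (unweighted or biomass-weighted),
    and provides the downstream correlation and regression analyses across
    services. Includes a niche-model generator for salt-marsh-like synthetic
    networks so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
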