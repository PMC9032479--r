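Package: salrmc
Title: Parallel Tempering Monte Carlo for Charged Colloidal Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Canonical-ensemble Monte Carlo machinery for isolated clusters of
    charged colloidal particles interacting through a short-range Morse
    attraction plus a long-range Yukawa repulsion (an SALR pair potential).
    Provides the pair potential and analytic gradients, Boerdijk-Coxeter
    tetrahelix (Bernal spiral) builders, basin-hopping global optimization,
    single-temperature Metropolis sampling with a cluster-rupture rejection
    rule and automatic step-size adaptation, parallel tempering with a
    deterministic even-odd replica-exchange schedule, heat-capacity curves
    from canonical energy fluctuations with peak and shoulder detection, and
    inherent-structure quenching with energy deduplication and structural
    motif classification (compact/spiral, beaded-necklace, linear/branched).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
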