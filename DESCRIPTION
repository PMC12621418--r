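Package: metascope
Title: Boolean Network-Expansion Analysis of Microbiome Metabolic Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the metabolic potential of soil microbiomes with
    stoichiometry-free (Boolean) genome-scale metabolic networks. Computes
    network-expansion scopes of community-wide (metagenome) and
    genome-resolved (MAG collection) models under designed nutrient
    conditions, builds binary producibility matrices across simulation
    grids, collapses metabolites into producibility groups, associates
    groups with environmental measurements through elastic-net regression,
    and enumerates all minimal cross-feeding communities able to produce
    environment-linked key metabolites, classifying members as essential
    or alternative syntrophic organisms. Includes a synthetic-world
    generator with ground-truth manifests for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
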