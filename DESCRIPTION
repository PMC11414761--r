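Package: dmepi
Title: Fitness and Gene-Expression Epistasis in Double Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates epistasis between pairs of beneficial mutations from
    competition-assay and RNA-seq data, as developed for Escherichia coli
    rho + rpoB double mutants adapting to thermal stress. Provides relative
    fitness estimation from colony counts, the multiplicative-null epistatic
    deviation with exact variance propagation for a product of independent
    estimates, diminishing-returns regression, an additive log-scale model of
    per-gene expression epistasis with genome-wide standardization and
    significance tiers, a four-way classifier of evolutionary expression
    change (restored, unrestored, reinforced, novel), a signed weighted
    coexpression-network stage (soft thresholding, topological overlap,
    module detection, eigengenes, module membership, intramodular
    connectivity, hub genes), connectivity comparisons against protein-protein
    interaction networks, and synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
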