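Package: sfcoupling
Title: Genetic Architecture of Vertex-Wise Structure-Function Connectivity Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of vertex-wise structural-functional connectivity
    (SC-FC) coupling phenotypes on cortical surface meshes by a normalized
    inner product over functional-network patches, and downstream genetic
    analysis: genotype quality control, SNP- and pedigree-based genetic
    relationship matrices, AI-REML variance-component estimation (univariate
    heritability, bivariate genetic correlation, repeated-measures models),
    two-step mixed-linear-model genome-wide association, LD clumping and
    genomic locus definition with cytoband assignment, network enrichment,
    distance decay of genetic correlation, and sensitivity simulations on
    synthetic twin and sibling cohorts generated by gene dropping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
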