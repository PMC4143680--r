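Package: pathkin
Title: Pathway-Specific Genetic Relationship Matrix Screening on Pedigrees
Version: 0.1.0
Authors@R:
    person("pathkin", "developers", email = "pathkin@example.org",
           role = c("aut", "cre"))
Description: Screens gene pathways for contributions to a quantitative trait
    in family data. For each pathway, an empirical pathway-specific genetic
    relationship matrix (PSGRM) is estimated from all sequence variants in or
    near the pathway's genes with a robust pairwise kinship estimator, added
    as a second variance component alongside the expected pedigree kinship in
    a multivariate-normal mixed model, and tested with a single
    degree-of-freedom boundary likelihood-ratio test whose null reference is
    a 50:50 mixture of a point mass at zero and a 1-df chi-square. Includes
    gene-set to genomic-region mapping, VCF genotype extraction, founder-based
    principal components with pedigree projection, calibration diagnostics
    (kinship deviation summaries, QQ/genomic inflation), and a gene-dropping
    simulator that generates pedigrees, genotypes and phenotypes with known
    variance fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    optparse,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
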