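Package: extremescan
Title: Genome-Wide Association and Phenome Scans on Polygenic Risk Score Extremes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a phenotype-agnostic extreme-polygenic-risk study
    design: clumping-and-thresholding polygenic risk scores are built from
    base GWAS summary statistics, the top and bottom tails of the score
    distribution are contrasted by covariate-adjusted logistic association,
    genomic risk loci are defined with a FUMA-style three-tier clumping
    hierarchy and classified against the base study, and the extreme groups
    are further characterised by hypergeometric gene-set enrichment, LD score
    regression (heritability and genetic correlation with block-jackknife
    errors) and a PHESANT-style phenome-wide scan with Bonferroni correction.
    A synthetic-data module generates block-LD genotypes, liability-threshold
    phenotypes, noisy external summary statistics, gene annotations and
    mixed-type trait tables with known ground truth, so the whole design is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, Genetics, StatisticalMethod
RoxygenNote: 7.3.3
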