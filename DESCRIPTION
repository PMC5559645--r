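Package: phyloCCF
Title: Multi-Sample Subclonal Reconstruction and Tumor Phylogenetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs tumor evolution from multi-sample somatic mutation
    data. Converts variant read counts to cancer cell fractions using purity
    and allele-specific copy number, clusters mutations across related samples
    with a multi-dimensional Dirichlet-process binomial mixture, orders
    clusters into a rooted phylogenetic tree by the pigeonhole principle,
    times whole-genome duplication with a binomial mixture EM and bootstrap
    confidence intervals, refits consensus mutational signatures to per-branch
    spectra by exhaustive subset search with non-negative least squares, and
    applies rule-based driver mutation annotation with cohort enrichment
    tests. Includes a synthetic multi-sample cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    vcfR,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SomaticMutation, CopyNumberVariation, Phylogenetics, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MutationSet.R'
    'RcppExports.R'
    'ccf.R'
    'dpcluster.R'
    'phylogeny.R'
    'drivers.R'
    'io.R'
    'methods-accessors.R'
    'signatures.R'
    'wgd.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
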