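Package: phenopop
Title: Temporal Isolation, Hybridization and Divergence Scans for
    Sympatric Insect Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying temporal (allochronic) reproductive
    isolation between closely related insect taxa sampled by interval
    trapping, and for locating genomic regions of elevated divergence.
    Provides SNP genotype input/output and filtering, principal component
    and maximum-likelihood admixture analysis with cluster-number
    selection, posterior classification of individuals into parental and
    hybrid categories, flight-period co-occurrence indices at two spatial
    grains, degree-day phenology by single triangulation with
    logger/station temperature calibration, a Bayesian F-ST outlier scan,
    latent-factor genotype-environment association scans, and a synthetic
    data generator that emulates a two-taxon trapping study for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
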