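Package: admixsel
Title: Multi-Locus Selection Inference from Local Ancestry in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies natural selection at multiple linked sites
    in admixed populations that arose from a single admixture pulse. Expected
    local-ancestry transition probabilities along a chromosome are computed
    numerically by evolving the distribution of ancestry haplotypes over the
    selected sites plus flanking ancestry-informative markers; model
    likelihoods on read-pileup or genotype data are evaluated with a hidden
    Markov model, and the number, positions and selection coefficients of
    selected sites are chosen by a two-stage Nelder-Mead optimizer combined
    with an iterative, simulation-calibrated likelihood-ratio procedure. A
    tract-based forward Wright-Fisher simulator is included so all validation
    can run on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
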